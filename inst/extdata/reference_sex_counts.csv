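group,male_n,total_n
single,76164,152017
combination,28173,54842
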