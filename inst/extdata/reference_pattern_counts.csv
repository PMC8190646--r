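group,pattern,n
single,ACE,60929
single,DEX,55847
single,IBU,35241
combination,ACE-DEX,28065
combination,ACE-IBU,22277
combination,IBU-DEX,3295
combination,ACE-IBU-DEX,1205
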