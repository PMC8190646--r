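name,code
ace,ACE
acetaminophen,ACE
paracetamol,ACE
tylenol,ACE
setopen,ACE
champ,ACE
ibu,IBU
ibuprofen,IBU
brufen,IBU
ibuprophen,IBU
dex,DEX
dexibuprofen,DEX
maxibupen,DEX
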