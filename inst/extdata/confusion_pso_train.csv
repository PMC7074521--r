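"","Adel","Arman","Azad"
"Adel",114418,3582,0
"Arman",0,115000,0
"Azad",936,0,117064
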