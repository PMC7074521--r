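"","Adel","Arman","Azad"
"Adel",18841,159,0
"Arman",89,18911,0
"Azad",0,0,19000
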