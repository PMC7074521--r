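"","Adel","Arman","Azad"
"Adel",58059,895,46
"Arman",601,57381,18
"Azad",235,0,59765
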