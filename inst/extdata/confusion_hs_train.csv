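"","Adel","Arman","Azad"
"Adel",116841,1159,0
"Arman",0,115000,0
"Azad",0,0,118000
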