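"","Adel","Arman","Azad"
"Adel",57854,1048,98
"Arman",852,57147,1
"Azad",386,0,59614
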