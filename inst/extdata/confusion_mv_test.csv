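"","Adel","Arman","Azad"
"Adel",58184,804,12
"Arman",508,57490,2
"Azad",266,0,59734
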