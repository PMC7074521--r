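"","Adel","Arman","Azad"
"Adel",117074,926,0
"Arman",753,114247,0
"Azad",0,0,118000
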