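"","Adel","Arman","Azad"
"Adel",18847,153,0
"Arman",0,18804,196
"Azad",0,289,18711
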