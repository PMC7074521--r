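"","Adel","Arman","Azad"
"Adel",18721,272,7
"Arman",68,18932,0
"Azad",741,0,18259
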