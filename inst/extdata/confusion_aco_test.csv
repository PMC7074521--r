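"","Adel","Arman","Azad"
"Adel",58059,895,46
"Arman",656,57315,29
"Azad",243,0,59757
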