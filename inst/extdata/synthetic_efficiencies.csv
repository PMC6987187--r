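gene,efficiency_percent
g01,91
g02,95.5
g03,100
g04,104.5
g05,109
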