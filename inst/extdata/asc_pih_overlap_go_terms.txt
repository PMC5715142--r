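GO:0002576
GO:0030168
GO:0007596
GO:0045429
GO:0001525
GO:0051000
GO:0035924
GO:0048010
GO:0045766
GO:0043066
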