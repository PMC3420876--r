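lncrna	orf_aa
enod40	0
COLDAIR	34
COOLAIR_short	38
COOLAIR_long	43
linc1257	68
NRON	71
HOTTIP	86
NEAT1	97
RepA	105
HOTAIR	106
AIR	112
XIST	136
TSIX	151
KCNQ1QT	289
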