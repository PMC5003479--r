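ATF	1.0
7	7
"Type=GenePix ArrayList V1.0"
"BlockCount=1"
"SlideWidth=4000"
"SlideHeight=4000"
"SpotDiameter=300"
"EdgeGap=200"
"Margin=500"
"Block"	"Row"	"Column"	"ID"	"Name"	"X"	"Y"
1	1	1	"S00001"	"negative_control|NTC"	150.0	150.0
1	1	2	"S00002"	"test|siRNA_A"	650.0	150.0
1	2	1	"S00003"	"test|siRNA_B"	150.0	650.0
1	2	2	"S00004"	"blank|"	650.0	650.0
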