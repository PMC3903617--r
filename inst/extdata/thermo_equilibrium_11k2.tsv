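# Published van't Hoff equilibrium thermodynamics of 11K2 scFv binding
# MCP-1: dH (kcal/mol) and -T dS (kcal/mol, at 25 C) for wild type and
# the five affinity-improved muteins.
variant	dH	mTdS
WT	-7.3	-5.0
L-N31R	-25.6	12.3
L-S53D	-13.3	0.6
L-S53E	-15.1	2.4
L-T56D	-11.7	-1.1
L-T56E	-14.5	1.9
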