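# Published kinetic parameters of the binding of 11K2 scFv (wild type and
# twelve single-muteins) to immobilized MCP-1 at 25 C, from SPR global
# Langmuir 1:1 fits. Units: kon 1/(M s); koff 1/s; KD M (as printed,
# which for two rows is inconsistent with koff/kon and is flagged by the
# analysis rather than corrected). improved_printed: as published.
variant	T_K	kon	koff	KD	improved_printed
WT	298.15	1.4e5	1.0e-4	8.0e-10	-
H-L27R	298.15	1.4e5	3.3e-4	2.4e-9	NO
H-L27K	298.15	1.1e5	3.9e-4	3.5e-9	NO
H-N28D	298.15	1.6e4	1.6e-4	1.0e-9	NO
H-N28Q	298.15	2.2e5	1.9e-3	8.5e-9	NO
H-D31E	298.15	3.0e4	1.5e-4	5.0e-9	NO
L-Y30K	298.15	1.3e5	3.1e-4	2.5e-9	NO
L-N31R	298.15	1.3e5	2.2e-5	1.7e-10	YES
L-N31K	298.15	3.4e5	9.8e-2	2.9e-7	NO
L-S53D	298.15	9.0e4	5.5e-5	6.1e-10	YES
L-S53E	298.15	7.3e4	1.4e-5	1.9e-10	YES
L-T56D	298.15	2.2e5	8.6e-5	3.9e-10	YES
L-T56E	298.15	1.0e5	2.6e-5	2.5e-10	YES
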