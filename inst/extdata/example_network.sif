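# Small example of a signed regulatory network in SIF3 format:
# source <whitespace> effect <whitespace> target
# effect tokens: activation/activates/->/1/+  inhibition/inhibits/-|/-1/-
# Cell-cycle / proliferation regulators often discussed in breast cancer.
TFDP1	activation	CDKN2A
TFDP1	activation	RRM2
TFDP1	activation	CDC6
TFDP1	activation	TK1
TFDP1	activation	TYMS
E2F1	activation	CDC6
E2F1	activation	CCNE2
E2F1	activation	CDC25A
FOS	activation	MMP1
JUN	activation	MMP1
FOSB	activation	MMP9
FOXA1	activation	XBP1
CDKN2A	inhibition	CDK4
CDKN1A	inhibition	CCNE2
RB1	inhibition	E2F1
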