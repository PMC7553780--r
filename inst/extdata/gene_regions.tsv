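gene	scaling_trait	variance_explained	variance_explained_ldl
HMGCR	LDL	0.004	0.004
PCSK9	LDL	0.012	0.012
LDLR	LDL	0.010	0.010
NPC1L1	LDL	0.002	0.002
APOC3	TG	0.010	0.001
LPL	TG	0.009	0.0005
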