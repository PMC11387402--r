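comparison	group_a	group_b	fc_lpc26	fc_c26
CALD_vs_noCALD	CALD	noCALD	1.52	1.21
CALD_vs_noCALD_gt55	CALD	noCALD_gt55	2.24	1.45
AI_vs_noAI	AI	noAI	1.58	1.16
AI_vs_noAI_gt55	AI	noAI_gt55	2.01	1.33
severe_vs_mild_males	severe_males	mild_males	1.82	1.4
severe_vs_mild_females	severe_females	mild_females	1.43	1.26
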