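group	lpc26_mean	lpc26_median	lpc26_min	lpc26_max	c26_mean	c26_median	c26_min	c26_max
CALD	601	571	190	928	5	5	3.2	6.8
noCALD	395	356	85	863	4.2	4	2.2	6.5
noCALD_gt55	269	254	125	468	3.5	3.4	2.4	4.3
AI	536	516	130	928	4.6	4.6	2.3	6.8
noAI	341	316	85	928	4	3.7	2.2	6.5
noAI_gt55	267	242	125	398	3.5	3.4	2.4	4.3
mild_males	259	231	125	398	3.4	3.3	2.4	4.3
severe_males	472	411	189	832	4.8	4.7	3.4	6.5
severe_females	337	305	145	747	4.1	4	2.7	5.8
mild_females	235	213	85	402	3.2	3.3	2.1	4.7
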