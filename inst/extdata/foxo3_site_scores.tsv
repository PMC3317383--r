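position	residue	phos_cat	phos_threshold	glyc_cat	sa	conserved	kinases
7	S	above	0.5	above	NA	TRUE	
12	S	above	0.5	below	0.8	TRUE	ERK1;AKT
26	S	above	0.5	above	4.8	TRUE	GSK3
30	S	below	0.5	below	NA	TRUE	
43	S	above	0.5	below	1.7	TRUE	Cdk5
48	S	above	0.5	above	NA	TRUE	
55	S	below	0.5	below	NA	TRUE	
110	S	above	0.5	above	NA	TRUE	
144	S	below	0.5	above	NA	TRUE	
151	S	above	0.5	above	1.7	TRUE	PKC;PKA
152	S	above	0.5	below	NA	TRUE	
161	S	above	0.5	below	NA	TRUE	
172	S	above	0.5	below	NA	TRUE	
173	S	above	0.5	below	3.6	TRUE	Cdk5;Cdc2
200	S	above	0.5	below	NA	TRUE	
209	S	above	0.5	below	1.9	TRUE	PKC
243	S	above	0.5	below	NA	TRUE	
253	S	above	0.5	above	0.6	TRUE	AKT;PKA
257	S	above	0.5	below	NA	TRUE	
280	S	above	0.5	above	2.3	TRUE	CK2;GSK3
284	S	above	0.5	below	1.9	TRUE	ERK
294	S	above	0.5	near	1.4	TRUE	Cdk5;Cdc2;ERK1;p38 MAPK
297	S	above	0.5	above	NA	TRUE	
299	S	above	0.5	below	NA	TRUE	
300	S	above	0.5	below	2.0	TRUE	CK2
311	S	below	0.5	above	NA	TRUE	
315	S	above	0.5	above	1.6	TRUE	AKT;Clk2
318	S	above	0.5	below	1.7	TRUE	CK1
321	S	below	0.5	above	1.9	TRUE	CK1
325	S	above	0.5	below	0.5	TRUE	ERK1
330	S	above	0.5	below	NA	TRUE	
344	S	above	0.5	above	0.6	TRUE	ERK1
349	S	below	0.5	above	NA	TRUE	
350	S	below	0.5	above	NA	TRUE	
351	S	below	0.5	above	0.6	TRUE	GSK3
353	S	above	0.5	below	0.7	TRUE	CK1;PKC;PKC delta
355	S	above	0.5	above	0.5	TRUE	ERK1;Cdk5
357	S	above	0.5	below	NA	TRUE	
359	S	above	0.5	above	NA	TRUE	
399	S	above	0.5	below	2.6	TRUE	ATMK;AMPK
402	S	above	0.5	below	1.9	TRUE	ERK1
411	S	below	0.5	above	NA	TRUE	
413	S	above	0.5	below	1.1	TRUE	AKT;PKC
421	S	below	0.5	above	0.5	TRUE	CK1
425	S	above	0.5	near	0.7	TRUE	Cdc2;Cdk5;GSK3;ERK1
428	S	below	0.5	above	NA	TRUE	
429	S	above	0.5	below	NA	TRUE	
432	S	above	0.5	below	0.5	TRUE	CK1
442	S	above	0.5	below	NA	TRUE	
446	S	above	0.5	below	NA	TRUE	
463	S	above	0.5	below	0.9	TRUE	CK1
476	S	below	0.5	above	NA	TRUE	
480	S	above	0.5	below	NA	TRUE	
482	S	above	0.5	below	NA	TRUE	
494	S	above	0.5	above	NA	TRUE	
497	S	below	0.5	above	0.6	TRUE	PKC
501	S	above	0.5	above	NA	TRUE	
547	S	below	0.5	above	NA	TRUE	
551	S	above	0.5	below	NA	TRUE	
553	S	above	0.5	below	1.2	TRUE	PKC
560	S	above	0.5	above	NA	TRUE	
563	S	below	0.5	above	NA	TRUE	
564	S	above	0.5	below	NA	TRUE	
567	S	above	0.5	below	0.7	TRUE	PKC
574	S	above	0.5	below	NA	TRUE	
577	S	above	0.5	above	0.7	TRUE	ATMK
584	S	below	0.5	above	NA	TRUE	
586	S	above	0.5	below	NA	TRUE	
588	S	above	0.5	below	0.6	TRUE	AMPK
591	S	above	0.5	below	0.7	TRUE	PKC;CK1
594	S	above	0.5	below	NA	TRUE	
609	S	above	0.5	below	NA	TRUE	
626	S	above	0.5	below	NA	TRUE	
644	S	above	0.5	near	NA	TRUE	
666	S	below	0.5	above	NA	TRUE	
667	S	above	0.5	above	NA	TRUE	
669	S	below	0.5	above	NA	TRUE	
32	T	above	0.5	near	0.5	TRUE	AKT;PKA
228	T	below	0.5	below	NA	TRUE	
276	T	below	0.5	above	NA	TRUE	
296	T	above	0.5	above	2.5	TRUE	PKC
331	T	above	0.5	below	1.0	TRUE	CK2
395	T	below	0.5	above	NA	FALSE	
404	T	below	0.5	above	NA	FALSE	
417	T	above	0.5	below	2.3	TRUE	PKC
418	T	below	0.5	above	NA	FALSE	
450	T	above	0.5	below	NA	TRUE	
469	T	above	0.5	below	NA	TRUE	
487	T	above	0.5	below	1.2	TRUE	DNA PK
498	T	below	0.5	above	NA	TRUE	
540	T	above	0.5	below	NA	TRUE	
582	T	above	0.5	above	1.0	TRUE	PKC;CK1
660	T	below	0.5	above	NA	TRUE	
162	Y	above	0.5	NA	0.6	TRUE	Lck
260	Y	above	0.5	NA	NA	TRUE	
416	Y	above	0.5	NA	NA	TRUE	
465	Y	above	0.5	NA	NA	TRUE	Grb2 SH2
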