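chrI	1000	1300	JUNC00001	60	+	1000	1300	255,0,0	2	50,50	0,250
chrI	2000	2400	JUNC00002	3	+	2000	2400	255,0,0	2	50,50	0,350
chrI	3000	3250	JUNC00003	9	-	3000	3250	255,0,0	2	50,50	0,200
chrI	4000	4380	JUNC00004	5	-	4000	4380	255,0,0	2	50,50	0,330
chrI	5000	5300	JUNC00005	35	+	5000	5300	255,0,0	2	50,50	0,250
chrII	1500	1800	JUNC00006	44	+	1500	1800	255,0,0	2	50,50	0,250
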