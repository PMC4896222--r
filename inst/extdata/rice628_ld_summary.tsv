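subpop	n_significant	ratio_pct	d0.0_0.2	d0.2_0.4	d0.4_0.6	d0.6_0.8	d0.8_1.0	mean_dprime
POP1	362	7	19	117	43	37	146	0.64
POP2	468	9.1	13	121	181	84	69	0.54
POP3	225	4.4	25	33	52	60	55	0.59
POP4	1507	29.3	53	277	578	436	163	0.55
POP5	804	15.6	23	185	282	102	212	0.59
POP6	992	19.3	90	83	348	326	145	0.57
POP7	791	15.4	119	91	314	180	87	0.52
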