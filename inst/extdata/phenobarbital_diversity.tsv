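sample_id	concentration_mM	history_id	H
pb0_r1	0	naive	9.96
pb0_r2	0	naive	10.39
pb0_r3	0	naive	10.55
pb0.25_r1	0.25	naive	10.18
pb0.25_r2	0.25	naive	10.36
pb0.25_r3	0.25	naive	10.43
pb1_r1	1	naive	8.17
pb1_r2	1	naive	7.57
pb1_r3	1	naive	8.00
pb2.5_r1	2.5	naive	7.68
pb2.5_r2	2.5	naive	7.33
pb2.5_r3	2.5	naive	8.06
pb12.5_r1	12.5	naive	8.00
pb12.5_r2	12.5	naive	7.52
pb12.5_r3	12.5	naive	7.93
pb0_after1.0_r1	0	after_1.0mM	10.13
pb0_after1.0_r2	0	after_1.0mM	9.75
pb0_after1.0_r3	0	after_1.0mM	10.26
pb0.25_after1.0_r1	0.25	after_1.0mM	9.35
pb0.25_after1.0_r2	0.25	after_1.0mM	10.22
pb0.25_after1.0_r3	0.25	after_1.0mM	9.11
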