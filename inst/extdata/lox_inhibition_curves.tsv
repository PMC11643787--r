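id	conc_uM	inhibition_pct
1	60	27.62
1	70	45.25
1	80	63.30
1	90	81.12
2	30	12.99
2	40	33.61
2	50	53.12
2	60	74.14
3	20	40.679
3	30	49.593
3	40	58.907
3	50	66.821
4	60	29.47
4	70	47.37
4	80	68.27
4	90	88.18
5	50	21.78
5	60	37.64
5	70	51.49
5	80	63.36
6	10	16.21
6	20	35.89
6	30	65.08
6	40	83.27
7	40	25.91
7	45	46.84
7	50	68.77
7	55	89.70
8	40	13.88
8	45	36.79
8	50	63.70
8	55	86.60
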