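# Published per-gene log2 ratios and linear fold changes for the two
# comparisons (patient tumours vs cell lines, patient tumours vs normal
# skeletal muscle), as printed in the source clinical study's result
# tables. Used to check log-ratio -> fold-change arithmetic.
gene	comparison	log_ratio	fold_change
SPP1	vs_cell_lines	5.608	48.757
SPP1	vs_muscle	4.823	28.308
CXCR4	vs_cell_lines	3.870	14.621
CXCR4	vs_muscle	3.700	12.999
CD14	vs_cell_lines	3.089	8.509
CD14	vs_muscle	2.431	5.391
FOS	vs_cell_lines	2.984	7.911
FOS	vs_muscle	2.346	5.086
TNFAIP3	vs_cell_lines	2.065	4.186
TNFAIP3	vs_muscle	1.411	2.659
SOCS3	vs_cell_lines	1.940	3.837
SOCS3	vs_muscle	1.793	3.464
HSPA6	vs_cell_lines	1.584	2.998
HSPA6	vs_muscle	1.353	2.554
IL8	vs_cell_lines	1.368	2.582
IL8	vs_muscle	1.500	2.828
IL23A	vs_cell_lines	1.259	2.393
IL23A	vs_muscle	1.336	2.525
STAT2	vs_cell_lines	1.259	2.393
STAT2	vs_muscle	1.336	2.525
LY96	vs_muscle	4.465	22.085
MIF	vs_muscle	3.843	14.352
JAK1	vs_muscle	2.961	7.786
MAPK7	vs_muscle	2.790	6.917
PGLYRP2	vs_muscle	2.589	6.017
ERLIN1	vs_muscle	2.235	4.709
PELI1	vs_muscle	2.117	4.337
SOCS4	vs_muscle	2.053	4.149
TRAF5	vs_muscle	1.984	3.955
IRF3	vs_muscle	1.889	3.703
MYD88	vs_muscle	1.846	3.596
SOCS2	vs_muscle	1.801	3.485
STAT6	vs_muscle	1.656	3.151
HMGB1	vs_muscle	1.585	2.999
MAPK1	vs_muscle	1.447	2.727
IL10RB	vs_muscle	1.278	2.426
IKBKB	vs_muscle	1.199	2.296
PELI2	vs_muscle	1.191	2.283
C5	vs_muscle	1.185	2.273
MAP4K4	vs_muscle	1.182	2.268
STAT1	vs_muscle	1.139	2.202
FOXP3	vs_muscle	1.112	2.161
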