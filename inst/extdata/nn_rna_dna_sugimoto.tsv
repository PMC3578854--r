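step	dH_kcal_mol	dS_cal_mol_K	dG37_kcal_mol	source
AA	-7.8	-21.9	-1.0	sugimoto1995_hybrid
AC	-5.9	-12.3	-2.1	sugimoto1995_hybrid
AG	-9.1	-23.5	-1.8	sugimoto1995_hybrid
AU	-8.3	-23.9	-0.9	sugimoto1995_hybrid
CA	-9.0	-26.1	-0.9	sugimoto1995_hybrid
CC	-9.3	-23.2	-2.1	sugimoto1995_hybrid
CG	-16.3	-47.1	-1.7	sugimoto1995_hybrid
CU	-7.0	-19.7	-0.9	sugimoto1995_hybrid
GA	-5.5	-13.5	-1.3	sugimoto1995_hybrid
GC	-8.0	-17.1	-2.7	sugimoto1995_hybrid
GG	-12.8	-31.9	-2.9	sugimoto1995_hybrid
GU	-7.8	-21.6	-1.1	sugimoto1995_hybrid
UA	-7.8	-23.2	-0.6	sugimoto1995_hybrid
UC	-8.6	-22.9	-1.5	sugimoto1995_hybrid
UG	-10.4	-28.4	-1.6	sugimoto1995_hybrid
UU	-11.5	-36.4	-0.2	sugimoto1995_hybrid
init	1.9	-3.9	3.1	sugimoto1995_hybrid
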