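step	dH_kcal_mol	dS_cal_mol_K	dG37_kcal_mol	source
AA	-7.9	-22.2	-1.00	santalucia1998_unified
AC	-8.4	-22.4	-1.44	santalucia1998_unified
AG	-7.8	-21.0	-1.28	santalucia1998_unified
AT	-7.2	-20.4	-0.88	santalucia1998_unified
CA	-8.5	-22.7	-1.45	santalucia1998_unified
CC	-8.0	-19.9	-1.84	santalucia1998_unified
CG	-10.6	-27.2	-2.17	santalucia1998_unified
CT	-7.8	-21.0	-1.28	santalucia1998_unified
GA	-8.2	-22.2	-1.30	santalucia1998_unified
GC	-9.8	-24.4	-2.24	santalucia1998_unified
GG	-8.0	-19.9	-1.84	santalucia1998_unified
GT	-8.4	-22.4	-1.44	santalucia1998_unified
TA	-7.2	-21.3	-0.58	santalucia1998_unified
TC	-8.2	-22.2	-1.30	santalucia1998_unified
TG	-8.5	-22.7	-1.45	santalucia1998_unified
TT	-7.9	-22.2	-1.00	santalucia1998_unified
init_AT	2.3	4.1	1.03	santalucia1998_unified
init_GC	0.1	-2.8	0.98	santalucia1998_unified
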