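# kind: DNA:DNA
# source: SantaLucia (1998) PNAS 95:1460-1465, unified nearest-neighbor parameters (Table 2)
# key: coding-strand dinucleotide, 5'->3'; parameters for that stack paired with its complement
# dH_kcal_mol: enthalpy of duplex formation per stack (kcal/mol)
# dS_cal_mol_K: entropy of duplex formation per stack (cal/(mol*K))
# melting free energy at temperature T is -(dH - T*dS) converted to kJ/mol
# reverse-complement pairs share one parameter set (e.g. CA and TG), as published
dinucleotide	dH_kcal_mol	dS_cal_mol_K
AA	-7.9	-22.2
AT	-7.2	-20.4
TA	-7.2	-21.3
CA	-8.5	-22.7
TG	-8.5	-22.7
GT	-8.4	-22.4
AC	-8.4	-22.4
CT	-7.8	-21.0
AG	-7.8	-21.0
GA	-8.2	-22.2
TC	-8.2	-22.2
CG	-10.6	-27.2
GC	-9.8	-24.4
GG	-8.0	-19.9
CC	-8.0	-19.9
TT	-7.9	-22.2
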