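# kind: RNA:DNA-mismatch (SYNTHETIC stand-in parameters)
# Stack parameters for an internal RNA:DNA mismatch at one position of the
# hybrid, for the four mismatch identities rA.dA, rC.dC, rG.dG and rU.dT
# (one covered mismatch per template deoxyribonucleotide).
# These are NOT measured literature values: each entry is the matched
# Sugimoto-1995 stack with its enthalpy shifted by a per-mismatch free-energy
# penalty (A +1.0, C +1.2, G +0.4, U +0.6 kcal/mol per stack; entropy kept),
# chosen inside the range reported for internal hybrid mismatches. Marked
# synthetic in the filename; replace with measured trimer-derived stacks when
# available.
# context: 5p = stack(5' neighbor, mismatch site); 3p = stack(mismatch site, 3' neighbor)
# neighbor: the matched RNA base flanking the mismatch (coding strand, T->U)
# mismatch: the erroneous RNA base
# melting free energy at temperature T is -(dH - T*dS) converted to kJ/mol
context	neighbor	mismatch	dH_kcal_mol	dS_cal_mol_K
5p	A	A	-7.3	-23.9
3p	A	A	-6.8	-23.2
5p	C	A	-6.0	-19.7
3p	C	A	-7.6	-22.9
5p	G	A	-6.8	-21.6
3p	G	A	-9.4	-28.4
5p	U	A	-10.5	-36.4
3p	U	A	-10.5	-36.4
5p	A	C	-7.9	-23.5
3p	A	C	-4.3	-13.5
5p	C	C	-15.1	-47.1
3p	C	C	-6.8	-17.1
5p	G	C	-11.6	-31.9
3p	G	C	-11.6	-31.9
5p	U	C	-9.2	-28.4
3p	U	C	-6.6	-21.6
5p	A	G	-5.5	-12.3
3p	A	G	-8.6	-26.1
5p	C	G	-8.9	-23.2
3p	C	G	-8.9	-23.2
5p	G	G	-7.6	-17.1
3p	G	G	-15.9	-47.1
5p	U	G	-8.2	-22.9
3p	U	G	-6.6	-19.7
5p	A	U	-7.2	-21.9
3p	A	U	-7.2	-21.9
5p	C	U	-8.4	-26.1
3p	C	U	-5.3	-12.3
5p	G	U	-4.9	-13.5
3p	G	U	-8.5	-23.5
5p	U	U	-7.2	-23.2
3p	U	U	-7.7	-23.9
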