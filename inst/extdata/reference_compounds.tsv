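# halonet reference compound library, version 1.0
# Main-text compounds 1-22 of the source study (azaphilones from Penicillium
# sclerotiorum SNB-CN111, ilicicolins from Neonectria discophora SNB-CN63).
# Entries without a printed molecular formula are kept name-only (formula NA)
# and are excluded from exact-mass matching; no formulas were invented.
# halogens column: semicolon-separated element symbols, or "none".
number	name	formula	family	halogens	note
1	ilicicolinal (LL-Z1272alpha)	C23H31ClO3	ilicicolin	Cl	chlorinated ilicicolin, [M+H]+ m/z 391.2028
2	ilicicolinic acid A	C23H31ClO4	ilicicolin	Cl	chlorinated ilicicolin, [M+H]+ m/z 407.1979
3	ilicicolinic acid C	NA	ilicicolin	Cl	annotated by MS/MS; formula not printed
4	sclerotiorin	C21H23ClO5	azaphilone	Cl	[M+H]+ m/z 391.1309
5	sclerotioramine	NA	azaphilone	Cl	annotated by MS/MS; formula not printed
6	5-chloroisorotiorin	NA	azaphilone	Cl	annotated by MS/MS; formula not printed
7	orsellinic acid	NA	ilicicolin	none	NR-PKS product; formula not printed
8	grifolic acid	C23H32O4	ilicicolin	none	prenyltransferase product, [M+H]+ m/z 373.2373
9	ilicicolin B (LL-Z1272beta)	C23H32O3	ilicicolin	none	[M+H]+ m/z 357.2422
10	azaphilone precursor (NR-PKS product)	C19H24O4	azaphilone	none	[M+H]+ m/z 317.1747
11	azaphilone intermediate (monooxygenase product)	C19H24O5	azaphilone	none	[M+H]+ m/z 333.1699
12	azaphilone scaffold intermediate	C19H22O4	azaphilone	none	[M+H]+ m/z 315.1594
13	acyltransferase product (sclerotiorin precursor)	C21H24O5	azaphilone	none	[M+H]+ m/z 357.1705
14	acetoacetylated intermediate	NA	azaphilone	none	not detected in extracts
15	Knoevenagel condensation product	C23H24O5	azaphilone	none	[M+H]+ m/z 381.1691
16	hydrogenated lactone intermediate	C23H26O5	azaphilone	none	[M+H]+ m/z 383.1859
17	isochromophilone I	NA	azaphilone	Cl	annotated; formula not printed
18	uncharacterized intermediate	NA	azaphilone	none	not characterized in main text
19	dehalo precursor of compound 20	C21H28O5	azaphilone	none	[M+H]+ m/z 361.2021
20	chlorinated azaphilone (pathway 3 product)	C21H27ClO5	azaphilone	Cl	[M+H]+ m/z 395.1626
21	chlorinated scaffold intermediate	C19H21ClO4	azaphilone	Cl	[M+H]+ m/z 349.1205
22	5-bromoisorotiorin	C23H23BrO5	azaphilone	Br	[M+H]+ obs m/z 459.0798, calcd 459.0802
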