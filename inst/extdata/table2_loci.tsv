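# Chromosomal locations of teleost connexin ohnolog pairs at the most
# connexin-rich chromosomes, one row per ohnolog copy slot (A/B), one
# column per species.  Cells: chromosome / linkage-group number; slashes
# join tandem multiplets on one chromosome (and one presumed duplication
# on different chromosomes, cx30.3 B in Ch); "?" = unplaced; "sc"- or
# 3-4 digit labels are scaffolds.  "-" = no copy.  Rows ordered by the
# eel (Aj) chromosome that anchors each co-occurrence block.
orthogroup	copy	Aj	Ch	Dr	Gm	Ga	Fr	Tn
gje1	A	19	15	20	21	18	18	-
gje1	B	-	14	-	-	-	-	-
cx34.5	A	19	15	20	21	18	1917	14
cx32.2	A	19	15/15	20	21	18	1917	14
cx28.9	A	19	15	20/20	21	18	1917	14
gja1	A	19	15	20	21	18	1725	?
gja1	B	7	14	17	7	-	-	-
gja10	A	19	14	20	?	18	16	?
gja10	B	-	19	-	?	12	8	-
gjb7	A	19	15	20	21	18	1688	14
gjd2*1	A	19	15	20	21	18	218	10
gjd2*1	B	7	14	17	5	15	-	-
gja9	A	7	19	17	22	10	7	21
gja9	B	sc68	?	16	6	20	12	?
cx35.4	A	7	19	17	22	10	2	-
cx35.4	B	4	14	-	5	15	12	10
cx34.4	A	7	19	17	22	10	2	-
cx34.4	B	4	14	-	5	15	12	10
gja4	A	7	19	19	22	10	10	21
gja4	B	4	-	-	-	-	-	-
cx28.6	A	7	19	17	22	10	10	21
cx28.6	B	4	14	19	5	15	15	10
cx39.9	A	8	8	5	10	4	14	7
cx39.9	B	15	20	-	7/7	7	15	17
gjb1	A	8	14	5	10	4	4	1
gjb1	B	15	20	14	7	7	15	12
gja8	A	2	9	1	20	1	21	14
gja8	B	-	?	7	16	6	?	-
gja5	A	2	9	16	20	1	21	14
gja5	B	-	?	17	16	6	?	-
cx30.3	A	2	8	2	9	14	1/1	2/2/2
cx30.3	B	14	8/2	1	-	20	11	5
gja3	A	2	8	2	11	14	3	8
gja3	B	14	8	1	-	20	11	5
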