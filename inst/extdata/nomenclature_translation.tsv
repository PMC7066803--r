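# Translation between the connexin nomenclature systems in mammals and
# teleosts: mammalian Greek / size (kDa) / alphabetic symbols, the amended
# teleost Greek proposal (a/b mark ohnolog pairs), and the names commonly
# found in databases.  "-" = no symbol in that system.
orthogroup	mammal_greek	mammal_size	mammal_alphabet	amended_teleost	common_teleost_greek	common_teleost_size
GJA1	GJA1	Cx43	CXNK1	gja1a,gja1b	gja1,gja1like	cx43,cx40.8
GJA2	-	-	-	gja2a,gja2b	gja3like	cx39.9
GJA3	GJA3	Cx46	CXNJ1	gja3a,gja3b	gja3,gja3like,gja3a,gja3b	cx48.5
GJA4	GJA4	Cx37	CXNH1	gja4a,gja4b	gja4	cx39.4
GJA5	GJA5	Cx40	CXNI	gja5a,gja5b	gja5,gja5like,gja5a,gja5b	cx41.8
GJA6	GJA6,GJA6P	Cx33,Cx43pX	CXNK2	-	-	-
GJA8	GJA8	Cx50	CXNL	gja8a,gja8b	gja8,gja8a,gja8b	cx44.1,cx44.2
GJA9	GJA9	Cx58	CXNM	gja9a,gja9b	gja9,gja9like	cx52.9,cx55.5
GJA10	GJA10	Cx62,Cx59	CXNN	gja10a,gja10b	gja10,gja10like	cx52.6,cx62,cx52.7
GJA11	-	-	-	gja11	-	cx32.7,cx34.5
GJA12	-	-	-	gja12	-	cx28.1,cx28.9
GJA13	-	-	-	gja13	-	cx32.2,cx32.3
GJB1	GJB1	Cx32	CXNG	gjb1a,gjb1b	gjb1,gjb1like	cx27.5,cx31.7
GJB2	GJB2	Cx26	CXNE	-	-	-
GJB3	GJB3	Cx31	CXNC	gjb3a,gjb3b	gjb3like	cx35.4
GJB4	GJB4	Cx30.3	CXNB	-	-	-
GJB5	GJB5	Cx31.1	CXNA	-	-	-
GJB6	GJB6	Cx30	CXNF	-	-	-
GJB7	GJB7	Cx25	CXND	gjb7	gjb7	cx25,cx28.8
GJB8	-	-	-	gjb8a,gjb8b	gjb2like,gjb6like	cx30.3,cx33.8
GJB9	-	-	-	gjb9a,gjb9b	gjb4like	cx28.6,cx30.9
GJB10	-	-	-	gjb10a,gjb10b	gjb4like	cx34.4
GJC1	GJC1	Cx45	CXNQ	gjc1a,gjc1b	gjc1,gjc1like,gjc1a,gjc1b	cx45
GJC2	GJC2	Cx47	CXNO	gjc2	gjc2	cx47.1
GJC3	GJC3	Cx31.3	CXNP1	-	-	-
GJC4	-	-	-	gjc4a,gjc4b	gjc1like	cx43.4,cx44.2
GJD1	-	-	-	gjd1a,gjd1b	gjd1a,gjd2like	-
GJD2	GJD2	Cx36	CXNS	gjd2a,gjd2b	gjd2,gjd2b,gjd2like	cx35,cx35.1
GJD3	GJD3	Cx31.9	CXNR	gjd3	gjd3,gjd3like	-
GJD4	GJD4	Cx40.1,Cx39	CXNU	gjd4a,gjd4b	gjd4,gjd4like	cx40.1
GJD5	GJD5	Cx39.2	-	gjd5a,gjd5b	gjd2like	-
GJD6	-	-	-	gjd6	gjd2like	cx36.7
GJE1	GJE1	Cx23	CXNT	gje1	gje1,gje1like	cx23
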