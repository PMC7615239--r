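##gff-version 3
chr1	chipsummit	gene	6030	9637	.	-	.	ID=SIMG0001
chr1	chipsummit	gene	15743	19110	.	-	.	ID=SIMG0002
chr1	chipsummit	gene	25160	27335	.	+	.	ID=SIMG0003
chr1	chipsummit	gene	33299	35395	.	+	.	ID=SIMG0004
chr1	chipsummit	gene	41436	43686	.	-	.	ID=SIMG0005
chr1	chipsummit	gene	49733	51365	.	+	.	ID=SIMG0006
chr1	chipsummit	gene	57542	60637	.	+	.	ID=SIMG0007
chr1	chipsummit	gene	66666	68816	.	+	.	ID=SIMG0008
chr1	chipsummit	gene	74855	77180	.	-	.	ID=SIMG0009
chr1	chipsummit	gene	83196	86266	.	+	.	ID=SIMG0010
chr1	chipsummit	gene	92343	93697	.	+	.	ID=SIMG0011
chr1	chipsummit	gene	99734	102357	.	-	.	ID=SIMG0012
chr1	chipsummit	gene	108452	109615	.	-	.	ID=SIMG0013
chr1	chipsummit	gene	115771	119439	.	-	.	ID=SIMG0014
chr1	chipsummit	gene	125471	128927	.	+	.	ID=SIMG0015
chr1	chipsummit	gene	134889	137790	.	+	.	ID=SIMG0016
chr1	chipsummit	gene	143808	145705	.	-	.	ID=SIMG0017
chr1	chipsummit	gene	151753	153352	.	+	.	ID=SIMG0018
chr1	chipsummit	gene	159453	161758	.	+	.	ID=SIMG0019
chr1	chipsummit	gene	167795	169725	.	-	.	ID=SIMG0020
chr1	chipsummit	gene	175726	177721	.	+	.	ID=SIMG0021
chr1	chipsummit	gene	183731	186744	.	+	.	ID=SIMG0022
chr1	chipsummit	gene	192860	194479	.	+	.	ID=SIMG0023
chr1	chipsummit	gene	200504	203043	.	-	.	ID=SIMG0024
chr1	chipsummit	gene	209099	210957	.	-	.	ID=SIMG0025
chr1	chipsummit	gene	216995	218252	.	+	.	ID=SIMG0026
chr1	chipsummit	gene	224230	226566	.	-	.	ID=SIMG0027
chr1	chipsummit	gene	232474	233953	.	-	.	ID=SIMG0028
chr1	chipsummit	gene	240056	242376	.	-	.	ID=SIMG0029
chr1	chipsummit	gene	248347	251417	.	+	.	ID=SIMG0030
chr1	chipsummit	gene	257479	258776	.	+	.	ID=SIMG0031
chr1	chipsummit	gene	264911	268363	.	+	.	ID=SIMG0032
chr1	chipsummit	gene	274380	277740	.	+	.	ID=SIMG0033
chr1	chipsummit	gene	283757	286071	.	+	.	ID=SIMG0034
chr1	chipsummit	gene	292117	293951	.	+	.	ID=SIMG0035
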