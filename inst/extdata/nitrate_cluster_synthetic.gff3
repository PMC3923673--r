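##gff-version 3
# Synthetic gene annotation for a 200 kb two-contig test genome (ctg01, ctg02).
# Models a nitrate-assimilation cluster: nitrate transporter (YNT1), nitrate
# reductase (YNR1), nitrite reductase (YNI1), adjacent beta-galactosidase
# (LAC1), with unrelated flanking genes.
ctg01	synthio	gene	30001	32000	.	+	.	ID=FLANK1;Name=flanking_gene_1
ctg01	synthio	gene	33001	34500	.	+	.	ID=YNT1;Name=nitrate_transporter
ctg01	synthio	gene	35001	36800	.	+	.	ID=YNR1;Name=nitrate_reductase
ctg01	synthio	gene	37001	38500	.	-	.	ID=YNI1;Name=nitrite_reductase
ctg01	synthio	gene	39001	40500	.	+	.	ID=LAC1;Name=beta_galactosidase
ctg01	synthio	gene	42001	44000	.	-	.	ID=FLANK2;Name=flanking_gene_2
ctg02	synthio	gene	10001	12000	.	+	.	ID=CTRL1;Name=control_gene
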