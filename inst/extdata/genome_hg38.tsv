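# Human genome reference table (hg38 / GRCh38).
# length: exact chromosome lengths in bp (GRCh38 primary assembly).
# centromere: approximate centromere midpoint in bp (UCSC hg38 centromere
#   track, rounded to 0.1 Mb); used only for pericentromeric-retention logic.
# genes: approximate protein-coding gene count per chromosome
#   (Ensembl annotation, ca. release 110); used for gene-density correlation.
chrom	length	centromere	genes
chr1	248956422	123400000	2058
chr2	242193529	93900000	1309
chr3	198295559	90900000	1078
chr4	190214555	50000000	752
chr5	181538259	48800000	876
chr6	170805979	59800000	1048
chr7	159345973	60100000	989
chr8	145138636	45200000	677
chr9	138394717	43000000	786
chr10	133797422	39800000	733
chr11	135086622	53400000	1314
chr12	133275309	35500000	1034
chr13	114364328	17700000	327
chr14	107043718	17200000	830
chr15	101991189	19000000	613
chr16	90338345	36800000	873
chr17	83257441	25100000	1197
chr18	80373285	18500000	270
chr19	58617616	26200000	1472
chr20	64444167	28100000	544
chr21	46709983	12000000	234
chr22	50818468	15000000	488
chrX	156040895	60600000	842
chrY	57227415	10400000	71
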