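# hand-built filtering fixture: 20 input pairs
# 2 exact duplicates, 3 same-fragment pairs, 4 cis pairs closer than 10 kb,
# 11 retained (6 cis, 5 trans); one retained pair sits exactly at 10 kb.
#chrom1	pos1	strand1	chrom2	pos2	strand2
chrA	1000	+	chrB	5000	-
chrA	1000	+	chrB	5000	-
chrA	25000	-	chrB	35000	+
chrB	35000	+	chrA	25000	-
chrA	41000	+	chrA	69000	-
chrA	500	+	chrA	15000	-
chrB	31000	+	chrB	59000	-
chrA	19000	+	chrA	21000	-
chrA	39500	+	chrA	40500	+
chrA	69500	-	chrA	70500	+
chrB	29000	+	chrB	30100	-
chrA	1000	+	chrA	95000	-
chrA	25000	+	chrA	45000	-
chrA	30000	+	chrA	5000	-
chrA	45000	+	chrB	10000	+
chrA	75000	-	chrB	40000	-
chrB	2000	+	chrB	45000	-
chrA	10000	+	chrA	21000	+
chrB	50000	+	chrA	50000	-
chrA	60000	+	chrA	70000	-
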