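primer_id	sequence	intended_family	intended_genes	orientation
IGHJ1-2-R	ATTGCCCAACTCCAGTCT	IGHJ1	IGHJ1,IGHJ2	reverse
IGHJ3-R	TATCATTATTCTAGATAG	IGHJ3	IGHJ3	reverse
IGHJ4-5-R	AACAGGTTTCGATCCGTA	IGHJ4	IGHJ4,IGHJ5	reverse
IGHJ6-R	AAAGAGGGAGAAAATACG	IGHJ6	IGHJ6	reverse
IGKJ1-R	GTACAGTTGCAGCGGTCC	IGKJ1	IGKJ1	reverse
IGKJ2-R	TAAAGAACCCCGGTTAGG	IGKJ2	IGKJ2	reverse
IGKJ3-R	AAGGTCGTTACATCCATT	IGKJ3	IGKJ3	reverse
IGKJ4-R	AGGGACGTGCACCAGGAG	IGKJ4	IGKJ4	reverse
IGKJ5-R	AGACACTCTGAAATACCT	IGKJ5	IGKJ5	reverse
IGLJ1-R	ATAGTAACGATGGTCGTA	IGLJ1	IGLJ1	reverse
IGLJ2-3-R	TACACAAGAAAGTTCAAA	IGLJ2	IGLJ2,IGLJ3	reverse
IGLJ7-R	GAAGGCATGTCTCTTCCT	IGLJ7	IGLJ7	reverse
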