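primer_id	sequence	intended_family	intended_genes	orientation
IGKV1a	RACATCCAGATGACCCAG	IGKV1	IGKV1-39	forward
IGKV1b	GMCATCCAGTTGACCCAG	IGKV1	IGKV1-9	forward
IGKV1c	GCCATCCRGATGACCCAG	IGKV1	IGKV1-5	forward
IGKV1d	GTCATCTGGATGACCCAG	IGKV1	IGKV1D-8	forward
IGKV3a	GAAATTGTGTTGACRCAG	IGKV3	IGKV3-20,IGKV3-11	forward
IGLV1a	GAAATAGTGATGACGCAG	IGLV1	IGLV1-47	forward
IGLV1b	CAGTCTGTGCTGACTCAG	IGLV1	IGLV1-40	forward
IGLV2	CAGTCTGTGYTGACGCAG	IGLV2	IGLV2-14	forward
IGLV3a	CAGTCTGCCCTGACTCAG	IGLV3	IGLV3-21	forward
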