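primer_id	sequence	intended_family	intended_genes	orientation
IGHV1a	CAGGTKCAGCTGGTGCAG	IGHV1	IGHV1-46	forward
IGHV1b	CAGGTCCAGCTTGTGCAG	IGHV1	IGHV1-3	forward
IGHV1c	SAGGTCCAGCTGGTACAG	IGHV1	IGHV1-24	forward
IGHV1d	CARATGCAGCTGGTGCAG	IGHV1	IGHV1-45	forward
IGHV2a	CAGATCACCTTGAAGGAG	IGHV2	IGHV2-5	forward
IGHV2b	CAGGTCACCTTGARGGAG	IGHV2	IGHV2-26	forward
IGHV3a	GARGTGCAGCTGGTGGAG	IGHV3	IGHV3-7	forward
IGHV3b	CAGGTGCAGCTGGTGGAG	IGHV3	IGHV3-30	forward
IGHV3c	GAGGTGCAGCTGTTGGAG	IGHV3	IGHV3-23	forward
IGHV4	CAGSTGCAGCTGCAGGAG	IGHV4	IGHV4-4	forward
IGHV5a	GARGTGCAGCTGGTGCAG	IGHV5	IGHV5-51	forward
IGHV6a	CAGGTACAGCTGCAGCAG	IGHV6	IGHV6-1	forward
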