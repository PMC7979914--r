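name	family	chain	segment	cdr_bounds	anchor
IGHV1-46	IGHV1	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV1-3	IGHV1	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV1-24	IGHV1	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV1-45	IGHV1	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV2-5	IGHV2	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV2-26	IGHV2	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV3-7	IGHV3	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV3-30	IGHV3	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV3-23	IGHV3	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV4-4	IGHV4	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV5-51	IGHV5	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHV6-1	IGHV6	heavy	V	0,75,75,99,99,150,150,174,174,288	288
IGHJ1	IGHJ1	heavy	J		6
IGHJ2	IGHJ2	heavy	J		6
IGHJ3	IGHJ3	heavy	J		6
IGHJ4	IGHJ4	heavy	J		6
IGHJ5	IGHJ5	heavy	J		6
IGHJ6	IGHJ6	heavy	J		6
IGKV1-39	IGKV1	kappa	V	0,75,75,99,99,150,150,174,174,288	288
IGKV1-9	IGKV1	kappa	V	0,75,75,99,99,150,150,174,174,288	288
IGKV1-5	IGKV1	kappa	V	0,75,75,99,99,150,150,174,174,288	288
IGKV1D-8	IGKV1D	kappa	V	0,75,75,99,99,150,150,174,174,288	288
IGKV3-20	IGKV3	kappa	V	0,75,75,99,99,150,150,174,174,288	288
IGKV3-11	IGKV3	kappa	V	0,75,75,99,99,150,150,174,174,288	288
IGKJ1	IGKJ1	kappa	J		6
IGKJ2	IGKJ2	kappa	J		6
IGKJ3	IGKJ3	kappa	J		6
IGKJ4	IGKJ4	kappa	J		6
IGKJ5	IGKJ5	kappa	J		6
IGLV1-47	IGLV1	lambda	V	0,75,75,99,99,150,150,174,174,288	288
IGLV1-40	IGLV1	lambda	V	0,75,75,99,99,150,150,174,174,288	288
IGLV2-14	IGLV2	lambda	V	0,75,75,99,99,150,150,174,174,288	288
IGLV3-21	IGLV3	lambda	V	0,75,75,99,99,150,150,174,174,288	288
IGLJ1	IGLJ1	lambda	J		6
IGLJ2	IGLJ2	lambda	J		6
IGLJ3	IGLJ3	lambda	J		6
IGLJ7	IGLJ7	lambda	J		6
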