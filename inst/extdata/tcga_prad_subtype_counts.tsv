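variable	category	subtype1	subtype2	subtype3
patients	all	206	146	146
gleason	2-6	13	19	21
gleason	7	92	70	84
gleason	8-10	101	57	41
path_n	N0	145	94	107
path_n	N1	40	26	13
lymph_nodes	positive	41	26	13
lymph_nodes	negative	138	91	98
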