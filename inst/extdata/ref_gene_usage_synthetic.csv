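gene,chain,frequency
IGHV3-23,heavy,0.13
IGHV3-30,heavy,0.12
IGHV1-69,heavy,0.11
IGHV1-69D,heavy,0.02
IGHV3-53,heavy,0.10
IGHV1-2,heavy,0.09
IGHV4-34,heavy,0.08
IGHV5-51,heavy,0.07
IGHV4-59,heavy,0.05
IGHV2-5,heavy,0.04
IGHV1-46,heavy,0.19
IGKV3-20,light,0.20
IGKV1-39,light,0.18
IGKV1-5,light,0.11
IGKV3-11,light,0.09
IGLV2-14,light,0.15
IGLV1-51,light,0.13
IGLV3-21,light,0.14
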