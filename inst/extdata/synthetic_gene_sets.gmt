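PLANTED_MODULE	genes of the planted differential edges	G0001	G0002	G0003	G0004	G0005	G0006
RANDOM_SET_01	random background gene set	G0002	G0017	G0024	G0026	G0029	G0031	G0032	G0035
RANDOM_SET_02	random background gene set	G0013	G0015	G0017	G0022	G0025	G0027	G0037	G0039
RANDOM_SET_03	random background gene set	G0004	G0005	G0009	G0014	G0016	G0026	G0033	G0039
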