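G0001	planted	G0002
G0001	background	G0026
G0002	background	G0023
G0002	background	G0028
G0002	background	G0032
G0003	planted	G0004
G0003	background	G0028
G0003	background	G0036
G0004	background	G0015
G0004	background	G0017
G0005	planted	G0006
G0005	background	G0007
G0006	background	G0036
G0007	background	G0018
G0007	background	G0027
G0008	background	G0037
G0009	background	G0021
G0009	background	G0036
G0009	background	G0039
G0010	background	G0020
G0010	background	G0029
G0011	background	G0023
G0012	background	G0018
G0012	background	G0029
G0014	background	G0026
G0014	background	G0039
G0017	background	G0026
G0018	background	G0020
G0018	background	G0022
G0019	background	G0030
G0020	background	G0037
G0022	background	G0031
G0023	background	G0026
G0023	background	G0032
G0023	background	G0036
G0026	background	G0028
G0026	background	G0030
G0026	background	G0033
G0027	background	G0040
G0030	background	G0034
G0031	background	G0035
G0033	background	G0040
G0035	background	G0037
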