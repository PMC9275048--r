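{"planted_edges":[{"predictor":"G0001","response":"G0002","A":1.5,"B":0},{"predictor":"G0003","response":"G0004","A":1.5,"B":0},{"predictor":"G0005","response":"G0006","A":1.5,"B":0}],"planted_response_pair":["G0001","G0002"],"response_effect":2,"seed":101}
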