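sample_id,subgroup,response,age
S001,A,Good,65.8425916684355
S002,A,Good,37.3044737961114
S003,A,Good,39.485133009444
S004,A,Good,28.1386850171005
S005,A,Good,68.3670943758129
S006,A,Good,61.5022488271328
S007,A,Good,43.9393842781344
S008,A,Good,55.5910854470172
S009,A,None,45.5162545238508
S010,A,None,68.9323447038025
S011,A,Good,53.8844952633969
S012,A,Good,53.8432053516748
S013,A,Good,50.8240845822662
S014,A,Good,71.4138955992097
S015,A,None,46.2089387403413
S016,A,Good,63.7553720739632
S017,B,None,61.4996654975014
S018,B,None,73.6308976760288
S019,B,None,27.5218276176855
S020,B,Good,68.3651864940129
S021,B,Good,46.0589971974373
S022,B,Good,42.9853027728759
S023,B,None,59.7002903354486
S024,B,None,32.3752247241331
S025,B,None,56.041437727933
S026,B,Good,55.2469454066559
S027,B,Good,31.5268995681271
S028,B,None,50.8997974772124
S029,B,Good,41.2211219799838
S030,B,None,54.5721778191376
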