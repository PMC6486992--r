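sample_id	total_reads	mapped_reads	junction_reads	n_circ
CK-L1	64941534	59683975	4115	337
CK-L2	47247952	43533334	3223	344
Na-L1	52711124	48504173	2814	277
Na-L2	56139180	51545903	3610	288
CK-R1	55226326	37769894	28936	807
CK-R2	48243900	33538249	29102	924
Na-R1	55918188	23369033	45248	819
Na-R2	65369878	36585168	37162	909
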