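sample_id	assay_call	assay_ratio	pct_skewed
Sample_1	Highly skewed	98:2	73.04
Sample_2	Highly skewed	95:5	22.43
Sample_3	Highly skewed	91:9	46.32
Sample_5	Moderately skewed	89:11	40.85
Sample_6	Moderately skewed	87:13	25.93
Sample_7	Random	53:47	2.35
Sample_8	Random	75:25	8.24
Sample_9	Random	66:34	2.94
Sample_11	Random	65:35	2.63
Sample_10	Random	60:40	18.37
Sample_14	Uninformative	NA	25.84
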