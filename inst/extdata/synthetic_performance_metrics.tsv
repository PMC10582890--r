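score_id	trait_id	trait_type	metric_kind	metric_value	publication_id
SPS000001	EFO_0001645	binary	or_per_sd	1.31	SPP000001
SPS000001	EFO_0001645	binary	AUROC	0.65	SPP000002
SPS000002	EFO_0001645	binary	Hazard Ratio (HR, per SD)	1.62	SPP000002
SPS000003	EFO_0000305	binary	or_per_sd	1.45	SPP000003
SPS000003	EFO_0000305	binary	Concordance Statistic (C-index)	0.62	SPP000003
SPS000004	EFO_0000305	binary	auc	0.61	SPP000004
SPS000005	EFO_0001360	binary	or_per_sd	0.91	SPP000005
SPS000006	EFO_0001360	binary	auc	0.45	SPP000005
SPS000007	EFO_0001360	binary	c_index	632	SPP000006
SPS000008	EFO_0004305	continuous	auc	0.71	SPP000006
SPS000009	EFO_0001645	binary	OR	1.88	SPP000007
SPS000010	EFO_0000305	binary	auc	0.72	SPP000007
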