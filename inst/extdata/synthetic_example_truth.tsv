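case_id	arm	true_status
case_001	1p	DELETED
case_001	19q	DELETED
case_002	1p	NORMAL
case_002	19q	NORMAL
case_003	1p	IMBALANCED
case_003	19q	IMBALANCED
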