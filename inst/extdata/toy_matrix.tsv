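gene_id	ctrl_01	ctrl_02	ctrl_03	case_01	case_02	case_03
up1	4	5	6	8	9	10
dn1	8	9	10	4	5	6
flat	7	7	7	7	7	7
small	7	7	7	7	7	8
null0	7	8	6	6	7	8
noisy	4	7	4	10	4	7
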