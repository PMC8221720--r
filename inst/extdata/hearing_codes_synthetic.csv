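code,code_system,fitting_flag
92557,CPT/HCPCS,0
92552,CPT/HCPCS,0
92567,CPT/HCPCS,0
V5010,CPT/HCPCS,0
V5011,CPT/HCPCS,1
V5014,CPT/HCPCS,1
V5090,CPT/HCPCS,0
V5261,CPT/HCPCS,0
389.10,ICD9,0
389.18,ICD9,0
388.30,ICD9,0
H90.3,ICD10,0
H93.19,ICD10,0
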