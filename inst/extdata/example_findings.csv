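patient_id,abnormality,n_segments
P001,ground_glass,2
P001,honeycombing,10
P002,ground_glass,6
P002,irregular_pleural_margins,3
P003,septal_subpleural_lines,1
P004,ground_glass,12
P004,irregular_pleural_margins,8
P004,septal_subpleural_lines,5
P004,honeycombing,4
P004,subpleural_cysts,2
P005,subpleural_cysts,1
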