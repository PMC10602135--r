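step_id,step_name,cumulative_visits,n_preceding_types,n_following_types,step_class
10,Descending & sigmoid colon mobilization (medial-to-lateral),86,13,11,nodal
11,Descending & sigmoid colon mobilization (lateral-to-medial),87,16,15,nodal
9,Rectal mobilization (medial-to-lateral),92,13,7,convergent
17,Rectal transection,39,6,12,divergent
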