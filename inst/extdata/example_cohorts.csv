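source_id,n,mean,sd
past_rct_control,420,0.04,0.98
registry_cohort,350,-0.06,1.05
open_label_extension,240,0.11,0.93
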