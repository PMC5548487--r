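report_id$drug_seq$indication
654502$1$Diabetes mellitus
5521616$1$Cardiac failure congestive
6380841$1$Diabetes mellitus
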