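report_id$reaction
654502$Diabetes mellitus
5521616$Cardiac failure congestive
6380841$Cardiac failure congestive
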