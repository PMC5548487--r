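report_id$drug_seq$role$verbatim_name
654502$1$PS$Rosiglitazone
5521616$1$PS$Rosiglitazone
6380841$1$PS$Rosiglitazone
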