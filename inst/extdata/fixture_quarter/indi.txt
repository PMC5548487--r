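report_id$drug_seq$indication
1001$1$Depression
1002$1$Depression
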