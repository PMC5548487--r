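report_id$drug_seq$role$verbatim_name
1001$1$PS$Fluoxetine HCl
1001$2$C$Aspirin
1002$1$PS$PROZAC 20mg
1003$1$PS$prozac (fluoxetine)
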