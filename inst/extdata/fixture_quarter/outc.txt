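report_id$outcome
1001$OT
1002$DE
1002$HO
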