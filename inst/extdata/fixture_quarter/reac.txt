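report_id$reaction
1001$Nausea
1001$Sexual dysfunction
1002$Myocardial infarction
1003$Gastric ulcer
9999$Headache
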