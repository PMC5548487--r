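Nausea
Sexual dysfunction
Myocardial infarction
Gastric ulcer
Headache
Depression
Diabetes mellitus
Cardiac failure congestive
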