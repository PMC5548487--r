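report_id$case_id$event_date$receipt_date$occupation$age$age_unit$sex
654502$1179039$2002-03-10$2002-04-01$MD$61$YR$F
5521616$162007$2004-06-02$2004-07-01$MD$58$YR$M
6380841$7085373$2009-01-20$2009-02-11$PH$66$YR$F
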