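report_id$case_id$event_date$receipt_date$occupation$age$age_unit$sex
1001$C100$2004-02-10$2004-03-01$MD$54$YR$F
1002$C101$20040511$20040601$LW$60$YR$M
1003$C101$2004-07-01$2004-08-15$CN$$$U
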