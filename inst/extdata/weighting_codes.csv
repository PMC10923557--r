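code,meaning,estimation,attested
101,date known only to the month; recorded as the earliest possible date,Estimated (dd),yes
102,date known only to the year; recorded as the earliest possible date,Estimated (dd/mm),no
150,death date taken from the surviving spouse's remarriage,Before this date,no
160,father's death inferred from a birth recorded as posthumous,Before this date,no
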