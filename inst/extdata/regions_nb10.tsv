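name	start	end
CDR1	27	36
CDR2	51	60
HV4	74	79
CDR3	99	118
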