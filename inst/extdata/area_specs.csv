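name,area_m2,seats,open,close,mean_waiting
Registered,115.02,12,08:00,18:00,30.54
Pediatrics,67.14,30,00:00,24:00,40.75
Internal medicine and Surgery,66.78,16,00:00,24:00,23.19
Inspection,44.73,1,08:00,18:00,7.84
Pharmacy,110.24,10,08:00,18:00,3.82
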