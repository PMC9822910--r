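area,Monday,Tuesday,Wednesday,Thursday,Friday,Saturday,Sunday,Sum
Registered,693,599,637,582,650,682,647,4490
Pediatrics,1485,1584,1387,1639,1541,1335,1465,10436
Internal medicine and Surgery,963,850,902,869,944,947,1037,6512
Inspection,183,136,169,103,114,225,229,1159
Pharmacy,75,91,89,78,68,87,78,566
Sum,3399,3260,3184,3271,3317,3276,3456,23163
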