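locus	assay	ct
dhd	cutrun	21.10
dhd	cutrun	21.24
dhd	mnase	24.62
dhd	mnase	24.55
Ubx	cutrun	20.05
Ubx	cutrun	20.18
Ubx	mnase	24.90
Ubx	mnase	24.87
Sas10	cutrun	23.95
Sas10	cutrun	24.08
Sas10	mnase	24.40
Sas10	mnase	24.31
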