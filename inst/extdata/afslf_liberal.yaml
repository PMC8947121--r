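name: AF/SLF (liberal termination fields)
cross_section_left: [160.6, 213.8]
cross_section_right: [51.5, 174.4]
anterior_field: ["44", "45", "6r", "IFSa", "IFSp", "FOP4", "47l", "p47r"]
posterior_field: ["PSL", "RI", "STV", "PFcm", "PF", "PFm", "PGi"]
density: 3.5e+05
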