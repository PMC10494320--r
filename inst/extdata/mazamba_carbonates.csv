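sample_id,height_cm,d13c_vpdb,d18o_vsmow,powder_mass_ug,carbonate_pct
GLP1-1NE-25,390,-6.8,26.2,112,91
GLP1-1NE-24,385,-9.1,25.8,144,87
GLP1-1NE-23,380,-7.7,26.4,121,89
GLP1-1NE-22,360,-8.6,26.0,129,95
GPL1-1NE-21,350,-7.1,25.7,366,16
GLP1-1NE-19,340,-6.4,25.7,146,96
GLP1-1NE-18,335,-7.0,26.0,135,91
GLP1-1NE-17,330,-7.0,25.6,135,93
GLP1-1NE-16,325,-7.5,25.5,170,89
GLP1-1NE-15,320,-6.7,26.1,139,88
GLP1-1NE-14,310,-9.3,25.9,159,78
GPL1-1NE-13,200,-7.6,25.7,149,83
GPL1-1NE-10,145,-7.4,25.4,123,50
GPL1-1NE-09,135,-7.5,26.0,131,62
GPL1-1NE-08,120,-6.3,26.2,136,79
GPL1-1NE-07,110,-5.9,26.5,131,86
GPL1-1NE-06,90,-6.3,26.3,150,80
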