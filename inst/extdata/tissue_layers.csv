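layer,thickness_cm,n,g,musp500,mie_b,water_frac,blood_frac,blood_so2,melanin_frac,cco_frac
epidermis,0.01,1.42,0.9,46,1.421,0.60,0.00,0.75,0.04,0
dermis,0.39,1.40,0.9,46,1.421,0.65,0.02,0.75,0.00,0
skull,0.70,1.43,0.9,22.9,0.716,0.35,0.01,0.75,0.00,0
csf,0.20,1.33,0.9,0.3,1.0,1.00,0.00,0.75,0.00,0
grey_matter,,1.37,0.9,24.2,1.611,0.80,0.04,0.70,0.00,1
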