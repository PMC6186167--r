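species,mycorrhizal_type,leaf_out_doy,sla_mm2_mg,max_height_m,wood_density_g_cm3,leaf_cn_ratio,seed_mass_mg
Acer pseudoplatanus,AMF,110,15.2,30,0.51,20.1,62
Aesculus hippocastanum,AMF,105,12.4,28,0.50,18.3,9800
Fraxinus excelsior,AMF,120,13.1,35,0.56,22.4,72
Prunus avium,AMF,108,14.6,25,0.49,19.2,180
Sorbus aucuparia,AMF,112,16.8,15,0.63,21.0,3.4
Betula pendula,EMF,100,18.3,28,0.53,23.5,0.2
Carpinus betulus,EMF,115,17.1,25,0.58,24.2,41
Fagus sylvatica,EMF,118,20.4,35,0.59,25.1,250
Quercus petraea,EMF,119,14.0,35,0.57,26.0,3400
Tilia platyphyllos,EMF,113,19.2,30,0.45,22.1,89
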