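name,stratum,leaf_form,leaf_thickness_mm,leaf_width_m,leaf_length_m,live_moisture,percent_dead,ignition_temperature,leaf_packing,clump_diameter_m,clump_separation_m,taxon_group
tussock_grass,near_surface,flat,0.30,0.005,0.30,100,0.30,260,120,0.25,0.10,monocotyledon
forb,near_surface,flat,0.35,0.015,0.08,150,0.05,260,50,0.20,0.10,dicotyledon
sclerophyll_shrub,elevated,flat,0.30,0.010,0.05,100,0.05,260,60,0.30,0.20,dicotyledon
mesic_shrub,elevated,flat,0.35,0.020,0.08,150,0.02,260,50,0.35,0.25,dicotyledon
wattle_midstorey,midstorey,flat,0.25,0.015,0.10,100,0.05,260,150,0.60,0.80,dicotyledon
teatree_midstorey,midstorey,flat,0.30,0.004,0.015,100,0.10,220,400,0.50,0.50,dicotyledon
eucalypt_canopy,canopy,flat,0.40,0.020,0.12,100,0.00,220,400,1.00,0.50,dicotyledon
broadleaf_eucalypt,canopy,flat,0.45,0.030,0.14,100,0.00,220,350,1.10,0.60,dicotyledon
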