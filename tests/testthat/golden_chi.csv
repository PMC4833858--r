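drug,polymer,delta_drug_mpa05,delta_poly_mpa05,molar_volume_cm3_mol,temperature_k,chi,logd,logd_estimated,zone
drug_CA,PLGA_repeat,20.6124625,24.0861339,197.8,310.15,0.925597002,3,FALSE,slow_release
drug_C12,PLGA_repeat,17.9389176,24.0861339,298.1,310.15,4.36854846,6,FALSE,intermediate
drug_OLA,PLGA_repeat,17.864625,24.0861339,362.5,310.15,5.44148764,8.5,FALSE,slow_release
drug_PLGA2k,PLGA_repeat,23.2536342,24.0861339,240.6,310.15,0.0646668811,4,FALSE,slow_release
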