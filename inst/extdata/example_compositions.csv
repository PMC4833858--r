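name,supplied_logd,CH3,CH2,CH,phenyl,COO,COOH,O,OH
PLGA_repeat,,1,1,1,,2,,,
drug_CA,3,1,4,,1,,1,,
drug_C12,6,1,12,,1,,,,
drug_OLA,8.5,1,16,,1,,,,
drug_PLGA2k,4,2,2,2,1,4,,,
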