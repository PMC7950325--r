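"module_name","start","end","functional_domain"
"FNII_1",18,56,"collagen-binding"
"FNI_3",72,82,"fibrin-binding-1"
"FNII_2",100,112,"collagen-binding"
"FNIII_2",130,162,"matrix-assembly"
"FNI_11",178,211,"fibrin-binding-2"
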