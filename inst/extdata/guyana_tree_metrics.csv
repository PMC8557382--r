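tree_id,dbh_cm,height_m,species
40_06,47.5,33.2,Licania hypoleuca
40_10,30.7,26.6,Ocotea puberula
40_11,36.5,23.8,Jacaranda copaia
40_12,36.5,27.0,Eperua falcata
40_24,35.1,28.8,Licania guianensis
40_25,34.4,28.2,Aspidosperma excelsum
60_06,57.0,35.7,Emmotum fagifolium
60_08,52.5,32.6,Siparuna surinamensis
60_12,52.1,30.0,Eperua falcata
60_20,52.7,25.6,Chlorocardium rodiei
60_21,58.0,30.4,Emmotum fagifolium
60_22,59.5,31.4,Chlorocardium rodiei
80_05,82.0,32.0,Eperua falcata
80_21,80.0,37.8,Mora gonggrijpii
80_22,75.0,28.7,Chlorocardium rodiei
100_05,102.0,48.0,Bombax globosum
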