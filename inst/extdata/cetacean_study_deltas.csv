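specimen_id,species,tissue,delta_glx_phe,tp_sc,tp1,tp1_sd,tp2,tp2_sd,tp3,tp3_sd,tp4,tp4_sd
bw_bal_01,bowhead,baleen,12.40,3.2,2.2,0.3,1.9,0.3,2.6,0.3,2.4,0.6
bw_bal_02,bowhead,baleen,12.75,3.2,2.2,0.3,1.9,0.3,2.7,0.3,2.5,0.6
bw_skn_01,bowhead,skin,14.47,3.2,2.5,0.3,1.9,0.2,2.9,0.3,3.0,0.5
bw_skn_02,bowhead,skin,12.63,3.2,2.2,0.2,1.9,0.2,2.6,0.2,2.5,0.5
bw_skn_03,bowhead,skin,12.68,3.2,2.2,0.2,1.9,0.3,2.7,0.2,2.5,0.5
bw_skn_04,bowhead,skin,13.57,3.2,2.3,0.3,1.9,0.2,2.8,0.2,2.7,0.5
bw_skn_05,bowhead,skin,13.82,3.2,2.4,0.3,2.0,0.2,2.8,0.3,2.8,0.5
bw_skn_06,bowhead,skin,13.28,3.2,2.3,0.3,2.0,0.2,2.7,0.2,2.7,0.5
bw_skn_07,bowhead,skin,13.31,3.2,2.3,0.3,1.9,0.2,2.7,0.2,2.7,0.5
bw_skn_08,bowhead,skin,13.84,3.2,2.4,0.3,2.0,0.2,2.8,0.3,2.8,0.5
bw_skn_09,bowhead,skin,14.49,3.2,2.5,0.3,1.9,0.2,2.9,0.3,3.0,0.5
bw_skn_10,bowhead,skin,13.84,3.2,2.4,0.3,2.0,0.3,2.8,0.3,2.8,0.5
bel_skn_01,beluga,skin,20.16,4.0,3.2,0.4,3.2,0.4,3.6,0.3,4.6,0.6
bel_skn_02,beluga,skin,19.46,4.0,3.1,0.4,3.5,0.4,3.6,0.3,4.4,0.5
bel_skn_03,beluga,skin,19.76,4.0,3.2,0.4,3.4,0.4,3.6,0.3,4.5,0.6
bel_skn_04,beluga,skin,20.01,4.0,3.2,0.4,3.4,0.4,3.6,0.3,4.6,0.6
bel_den_01,beluga,dentine_collagen,17.10,4.0,2.8,0.3,2.6,0.3,3.2,0.3,3.7,0.5
bel_den_02,beluga,dentine_collagen,18.64,4.0,3.0,0.4,2.7,0.3,3.4,0.3,4.2,0.5
bel_den_03,beluga,dentine_collagen,18.17,4.0,2.9,0.3,2.7,0.3,3.4,0.3,4.1,0.5
bel_den_04,beluga,dentine_collagen,18.97,4.0,3.0,0.4,2.5,0.3,3.5,0.3,4.3,0.6
bel_den_05,beluga,dentine_collagen,20.73,4.0,3.3,0.4,2.7,0.3,3.7,0.4,4.8,0.6
bel_den_06,beluga,dentine_collagen,16.91,4.0,2.8,0.3,2.6,0.3,3.2,0.3,3.7,0.5
bel_den_07,beluga,dentine_collagen,18.88,4.0,3.0,0.4,2.7,0.3,3.5,0.3,4.3,0.5
bel_den_08,beluga,dentine_collagen,18.54,4.0,3.0,0.4,2.6,0.3,3.4,0.3,4.2,0.5
bel_den_09,beluga,dentine_collagen,18.14,4.0,2.9,0.3,2.7,0.3,3.4,0.3,4.0,0.5
cd_skn_01,common_dolphin,skin,11.20,4.2,2.0,0.2,3.1,0.4,2.5,0.2,2.1,0.5
cd_skn_02,common_dolphin,skin,13.87,4.2,2.4,0.3,2.8,0.3,2.8,0.3,2.8,0.5
cd_skn_03,common_dolphin,skin,11.28,4.2,2.0,0.2,3.1,0.4,2.5,0.2,2.1,0.5
cd_skn_04,common_dolphin,skin,9.23,4.2,1.8,0.2,2.8,0.3,2.2,0.2,1.5,0.5
cd_skn_05,common_dolphin,skin,13.22,4.2,2.3,0.3,3.0,0.3,2.7,0.2,2.6,0.5
cd_skn_06,common_dolphin,skin,17.55,4.2,2.9,0.3,3.0,0.3,3.3,0.3,3.9,0.5
cd_skn_07,common_dolphin,skin,11.24,4.2,2.0,0.2,2.7,0.3,2.5,0.2,2.1,0.5
cd_skn_08,common_dolphin,skin,18.02,4.2,2.9,0.3,3.0,0.4,3.4,0.3,4.0,0.5
cd_skn_09,common_dolphin,skin,17.22,4.2,2.8,0.3,2.9,0.3,3.3,0.3,3.8,0.5
fe_den_01,killer_whale_fe,dentine_collagen,19.50,4.3,3.1,0.4,2.9,0.3,3.6,0.3,4.4,0.6
fe_den_02,killer_whale_fe,dentine_collagen,18.71,4.3,3.0,0.4,2.9,0.3,3.5,0.3,4.2,0.5
fe_den_03,killer_whale_fe,dentine_collagen,19.40,4.3,3.1,0.4,2.9,0.3,3.5,0.3,4.4,0.6
sw_skn_01,sperm_whale,skin,15.16,4.4,2.6,0.3,2.2,0.2,3.0,0.3,3.2,0.5
sw_skn_02,sperm_whale,skin,16.36,4.4,2.7,0.3,2.2,0.2,3.1,0.3,3.5,0.5
sw_skn_03,sperm_whale,skin,15.27,4.4,2.6,0.3,2.2,0.2,3.0,0.3,3.2,0.5
sw_skn_04,sperm_whale,skin,17.73,4.4,2.9,0.3,2.6,0.3,3.3,0.3,3.9,0.5
sw_skn_05,sperm_whale,skin,14.97,4.4,2.5,0.3,2.0,0.2,3.0,0.3,3.1,0.5
sw_skn_06,sperm_whale,skin,15.15,4.4,2.6,0.3,2.3,0.3,3.0,0.3,3.2,0.5
sw_skn_07,sperm_whale,skin,14.99,4.4,2.5,0.3,2.0,0.2,3.0,0.3,3.1,0.5
sw_skn_08,sperm_whale,skin,11.95,4.4,2.1,0.2,1.6,0.2,2.6,0.2,2.3,0.5
sw_skn_09,sperm_whale,skin,12.64,4.4,2.2,0.2,1.9,0.2,2.7,0.2,2.5,0.5
sw_skn_10,sperm_whale,skin,18.57,4.4,3.0,0.3,3.0,0.4,3.4,0.3,4.2,0.5
sw_skn_11,sperm_whale,skin,13.62,4.4,2.3,0.3,2.0,0.2,2.8,0.3,2.8,0.5
sw_skn_12,sperm_whale,skin,16.67,4.4,2.8,0.3,2.5,0.3,3.2,0.3,3.6,0.5
sw_skn_13,sperm_whale,skin,12.84,4.4,2.2,0.3,2.1,0.2,2.7,0.2,2.5,0.5
sw_den_01,sperm_whale,dentine_collagen,15.30,4.4,2.6,0.3,2.6,0.3,3.0,0.3,3.2,0.5
sw_den_02,sperm_whale,dentine_collagen,15.80,4.4,2.6,0.3,2.6,0.3,3.1,0.3,3.4,0.5
sw_den_03,sperm_whale,dentine_collagen,16.10,4.4,2.7,0.3,2.5,0.3,3.1,0.3,3.5,0.5
sw_den_04,sperm_whale,dentine_collagen,13.60,4.4,2.3,0.3,2.5,0.3,2.8,0.3,2.7,0.5
sw_den_05,sperm_whale,dentine_collagen,17.10,4.4,2.8,0.3,2.5,0.3,3.2,0.3,3.7,0.5
sw_den_06,sperm_whale,dentine_collagen,15.20,4.4,2.6,0.3,2.4,0.3,3.0,0.3,3.2,0.5
mme_den_01,killer_whale_mme,dentine_collagen,13.36,5.0,2.3,0.3,2.2,0.2,2.7,0.3,2.7,0.5
mme_den_02,killer_whale_mme,dentine_collagen,13.95,5.0,2.4,0.3,2.4,0.3,2.8,0.3,2.8,0.5
mme_den_03,killer_whale_mme,dentine_collagen,12.51,5.0,2.2,0.2,2.4,0.3,2.6,0.2,2.4,0.5
mme_den_04,killer_whale_mme,dentine_collagen,14.03,5.0,2.4,0.3,2.3,0.3,2.8,0.3,2.9,0.5
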