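name,lyophilizer,kc_cal_s_K_cm2,kp_cal_s_K_cm2_Torr,kd_per_Torr,fixed_kv_cal_s_K_cm2
Schott 6R,Millrock REVO,2.75e-4,8.93e-4,0.46,
5800W,Modified laboratory lyophilizer,2.64e-4,33.2e-4,3.64,
5816W,Modified laboratory lyophilizer,2.03e-4,33.2e-4,3.97,
5303,Modified laboratory lyophilizer,1.52e-4,33.2e-4,6.97,
Warped stainless steel tray,Modified laboratory lyophilizer,0.6e-4,65.9e-4,27,
Wheaton 2mL cold TC,SP Scientific LyoStar II,,,,3.8e-4
Wheaton 2mL cold PG,SP Scientific LyoStar II,,,,2.7e-4
Wheaton 2mL warm TC,SP Scientific LyoStar II,,,,2.0e-4
Wheaton 2mL warm PG,SP Scientific LyoStar II,,,,1.9e-4
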