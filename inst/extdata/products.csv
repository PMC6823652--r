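name,csolid_g_mL,r0_cm2_h_Torr_g,a1_cm_h_Torr_g,a2_per_cm,t_pr_max_C,rho_solution_g_cm3,rho_solute_g_cm3
5% mannitol,0.05,1.4,16,0,-5,1.0,1.52
5% sucrose,0.05,0.208,15.29,1.6,-35,1.0,1.587
5% povidone,0.05,1.13,5,0,-5,1.0,1.2
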