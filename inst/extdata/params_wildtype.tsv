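ks_Ini	   0.0003104
k_elong	   0.0065300
P_elong	   0.0500000
km_Cori	   1.5637000
km_ccrM	   2.2763000
km_ctrA	   1.4645000
Ja_Ini	   1.0000000
Ji_Ini	   1.4565000
Jm_Cori	   0.9500000
Jm_ccrM	   0.9500000
Jm_ctrA	   0.9500000
Theta_CtrA	   6.0000000
Theta_DnaA	   0.5000000
Theta_Cori	   0.3080000
ks_IccrM	   0.1105000
kd_IccrM	   0.0696000
ks_ccrM	   0.2557000
kd_ccrM	   0.1005000
ks_dnaA	   0.1990000
kd_dnaA	   0.0693000
ks_gcrA	   5.4235000
kd_gcrA	   0.7342000
ks1_ctrA	   1.0035000
ks2_ctrA	   0.0937000
kd_ctrA	   0.0983000
ks_sciP	   0.5830000
kd_sciP	   0.0523000
Ja_ccrM_CtrA	   5.0000000
Ji_ccrM_SciP	   6.0000000
Ji_dnaA_GcrA	   3.0000000
Ja_gcrA_DnaA	   1.2500000
Ji_gcrA_CtrA	   5.0000000
Ja_ctrA_CtrA	   5.0000000
Ja_ctrA_GcrA	   3.0000000
Ji_ctrA_CtrA	   8.0000000
Ji_ctrA_SciP	   8.0000000
Ja_sciP_CtrA	   5.0000000
ks_CcrM	   0.0834000
kd_CcrM	   0.0700000
ks_DnaA	   0.0787000
kd_DnaA	   0.0700000
ks_GcrA	   0.0320000
kd_GcrA	   0.0220000
ks_SciP	   0.1294000
kd_SciP	   0.0673000
ks_CtrA	   0.0404000
kd_CtrA	   0.0020000
kd_CtrA_ClpXP	   0.0530000
Jd_CtrA_ClpXP	   4.0000000
kpho_CtrA	   4.2919000
kdepho_CtrA	   0.1130000
kpho_CckA	   1.0270000
kdepho_CckA	   0.9242000
k1_plus	   0.6072000
k1_minus	   3.3013000
k2_plus	   1.4375000
k2_minus	   0.8164000
k3_plus	 170.4913000
k3_minus	   2.3133000
kphos_PleD	   0.0460000
kdephos_PleD	   0.0414000
ks_CpdR	   1.2227000
kd_CpdR	   1.6152000
kphos_CpdR	   1.1239000
kdephos_CpdR	   1.3854000
ks_RcdA	   0.1642000
kd_RcdA	   0.2323000
ks_cdG	   0.0099000
kd_cdG	   0.9893000
ks_PleD	   0.0956000
kd_PleD	   0.1314000
ks_PdeA	   0.0120000
kd_PdeA	   0.5161000
Ja_CpdR_CtrA	  15.0000000
Jd_CpdR	   6.0000000
Ja_RcdA_CtrA	  15.0000000
Jd_RcdA	   2.0000000
Ja_PdeA_CtrA	   5.0000000
Jd_PdeA	   5.0000000
Ja_PleD_CtrA	   2.5000000
Ji_cdG_cdG	   0.2000000
CckA_T	   0.3000000
ClpXP	   1.0000000
alpha_PdeA	   7.0000000
alpha_PleD	1500.0000000
alpha_cdG	  10.0000000
plec_A1	  80.0900000
plec_w	   0.0130000
plec_phi1	   1.7400000
plec_A2	  78.7700000
plec_phi2	   4.8500000
ks_Zring_on	   0.0110000
Elong_ccrM	   0.2000000
Elong_ctrA	   0.3750000
Elong_term	   1.0000000
Zring_div	   1.0000000
T_target	 150.0000000
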