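# Parameter marshalling for the compiled RHS: order must match the
# #define layout in src/cellcycle.c exactly.
rhs_parm_names <- c(
  "ks_Ini", "k_elong", "P_elong", "km_Cori", "km_ccrM", "km_ctrA",
  "Ja_Ini", "Ji_Ini", "Jm_Cori", "Jm_ccrM", "Jm_ctrA",
  "Theta_CtrA", "Theta_DnaA", "Theta_Cori",
  "ks_IccrM", "kd_IccrM", "ks_ccrM", "kd_ccrM", "ks_dnaA", "kd_dnaA",
  "ks_gcrA", "kd_gcrA", "ks1_ctrA", "ks2_ctrA", "kd_ctrA",
  "ks_sciP", "kd_sciP",
  "Ja_ccrM_CtrA", "Ji_ccrM_SciP", "Ji_dnaA_GcrA", "Ja_gcrA_DnaA",
  "Ji_gcrA_CtrA", "Ja_ctrA_CtrA", "Ja_ctrA_GcrA", "Ji_ctrA_CtrA",
  "Ji_ctrA_SciP", "Ja_sciP_CtrA",
  "ks_CcrM", "kd_CcrM", "ks_DnaA", "kd_DnaA", "ks_GcrA", "kd_GcrA",
  "ks_SciP", "kd_SciP", "ks_CtrA", "kd_CtrA", "kd_CtrA_ClpXP",
  "Jd_CtrA_ClpXP", "kpho_CtrA", "kdepho_CtrA", "kpho_CckA", "kdepho_CckA",
  "k1_plus", "k1_minus", "k2_plus", "k2_minus", "k3_plus", "k3_minus",
  "kphos_PleD", "kdephos_PleD", "ks_CpdR", "kd_CpdR", "kphos_CpdR",
  "kdephos_CpdR", "ks_RcdA", "kd_RcdA", "ks_cdG", "kd_cdG",
  "ks_PleD", "kd_PleD", "ks_PdeA", "kd_PdeA",
  "Ja_CpdR_CtrA", "Jd_CpdR", "Ja_RcdA_CtrA", "Jd_RcdA",
  "Ja_PdeA_CtrA", "Jd_PdeA", "Ja_PleD_CtrA", "Ji_cdG_cdG",
  "CckA_T", "ClpXP", "alpha_PdeA", "alpha_PleD", "alpha_cdG",
  "plec_A1", "plec_w", "plec_phi1", "plec_A2", "plec_phi2")

rhs_parm_vector <- function(p, ks_Zring, plec_t0, qssa, armed) {
  c(unname(p[rhs_parm_names]),
    ks_Zring, plec_t0, as.numeric(qssa),
    unname(p[c("P_elong", "Elong_ccrM", "Elong_ctrA",
               "Elong_term", "Zring_div")]),
    as.numeric(armed))
}
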