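# Independent, term-by-term transcription of the published ODE table,
# deliberately written in a different style from the package RHS (explicit
# Hill helper calls, one equation per statement, no precomputation).  Used
# as the two-implementation oracle.

oracle_hill_a <- function(x, J, n) x^n / (J^n + x^n)
oracle_hill_i <- function(x, J, n) J^n / (J^n + x^n)

oracle_rhs <- function(t, y, p, ks_Zring = 0, plec_t0 = 0) {
  g <- function(nm) unname(y[[nm]])
  q <- function(nm) unname(p[[nm]])
  PleC <- max(0, q("plec_A1") * sin(q("plec_w") * (t - plec_t0) + q("plec_phi1")) +
                 q("plec_A2") * sin(q("plec_w") * (t - plec_t0) + q("plec_phi2")))
  d <- numeric(29)
  names(d) <- names(y)
  d["Ini"] <- q("ks_Ini") *
    (g("DnaA") / q("Theta_DnaA"))^4 /
    (q("Ja_Ini")^4 + (g("CtrAP") / q("Theta_CtrA"))^4 +
       (g("DnaA") / q("Theta_DnaA"))^4) *
    (1 + 1 / (q("Ji_Ini")^4 + (g("hCori") / q("Theta_Cori"))^4))
  d["Elong"] <- q("k_elong") * oracle_hill_a(g("Elong"), q("P_elong"), 4)
  d["Zring"] <- ks_Zring
  d["hCori"] <- -q("km_Cori") * oracle_hill_a(g("CcrM"), q("Jm_Cori"), 4) * g("hCori")
  d["hccrM"] <- -q("km_ccrM") * oracle_hill_a(g("CcrM"), q("Jm_ccrM"), 4) * g("hccrM")
  d["hctrA"] <- -q("km_ctrA") * oracle_hill_a(g("CcrM"), q("Jm_ctrA"), 4) * g("hctrA")
  d["IccrM"] <- q("ks_IccrM") *
    oracle_hill_a(g("CtrAP"), q("Ja_ccrM_CtrA"), 2) *
    oracle_hill_i(g("SciP"), q("Ji_ccrM_SciP"), 2) * g("hccrM") -
    q("kd_IccrM") * g("IccrM")
  d["mccrM"] <- q("ks_ccrM") * g("IccrM") - q("kd_ccrM") * g("mccrM")
  d["mdnaA"] <- q("ks_dnaA") * oracle_hill_i(g("GcrA"), q("Ji_dnaA_GcrA"), 2) *
    (2 - g("hCori")) - q("kd_dnaA") * g("mdnaA")
  d["mgcrA"] <- q("ks_gcrA") * oracle_hill_a(g("DnaA"), q("Ja_gcrA_DnaA"), 2) *
    oracle_hill_i(g("CtrAP"), q("Ji_gcrA_CtrA"), 2) - q("kd_gcrA") * g("mgcrA")
  d["msciP"] <- q("ks_sciP") * oracle_hill_a(g("CtrAP"), q("Ja_sciP_CtrA"), 2) -
    q("kd_sciP") * g("msciP")
  d["mctrA"] <- q("ks1_ctrA") * oracle_hill_a(g("GcrA"), q("Ja_ctrA_GcrA"), 2) *
    oracle_hill_i(g("CtrAP"), q("Ji_ctrA_CtrA"), 4) *
    oracle_hill_i(g("SciP"), q("Ji_ctrA_SciP"), 4) * g("hctrA") +
    q("ks2_ctrA") * oracle_hill_a(g("CtrAP"), q("Ja_ctrA_CtrA"), 2) -
    q("kd_ctrA") * g("mctrA")
  d["CcrM"] <- q("ks_CcrM") * g("mccrM") - q("kd_CcrM") * g("CcrM")
  d["DnaA"] <- q("ks_DnaA") * g("mdnaA") - q("kd_DnaA") * g("DnaA")
  d["GcrA"] <- q("ks_GcrA") * g("mgcrA") - q("kd_GcrA") * g("GcrA")
  d["SciP"] <- q("ks_SciP") * g("msciP") - q("kd_SciP") * g("SciP")
  deg <- q("kd_CtrA") + q("kd_CtrA_ClpXP") *
    oracle_hill_a(g("Complex3"), q("Jd_CtrA_ClpXP"), 2)
  d["CtrA"] <- q("ks_CtrA") * g("mctrA") - deg * g("CtrA") -
    q("kpho_CtrA") * g("CckAP") * g("CtrA") + q("kdepho_CtrA") * g("CtrAP")
  d["CtrAP"] <- -deg * g("CtrAP") +
    q("kpho_CtrA") * g("CckAP") * g("CtrA") - q("kdepho_CtrA") * g("CtrAP")
  d["CckAP"] <- q("kpho_CckA") * (q("CckA_T") - g("CckAP")) -
    q("kdepho_CckA") * (1 + q("alpha_cdG") * g("cdG")) * g("CckAP")
  d["Complex1"] <- q("k1_plus") * q("ClpXP") * g("CpdR") -
    q("k1_minus") * g("Complex1") -
    q("k2_plus") * g("Complex1") * g("RcdA") + q("k2_minus") * g("Complex2")
  d["CpdR"] <- q("ks_CpdR") * oracle_hill_a(g("CtrAP"), q("Ja_CpdR_CtrA"), 2) -
    q("kd_CpdR") * g("CpdR") * g("Complex1") / (q("Jd_CpdR") + g("Complex1")) +
    q("k1_minus") * g("Complex1") - q("k1_plus") * q("ClpXP") * g("CpdR") +
    q("kdephos_CpdR") * g("CpdRP") - q("kphos_CpdR") * g("CckAP") * g("CpdR")
  d["CpdRP"] <- -q("kd_CpdR") * g("CpdRP") * g("Complex1") /
    (q("Jd_CpdR") + g("Complex1")) +
    q("kphos_CpdR") * g("CckAP") * g("CpdR") - q("kdephos_CpdR") * g("CpdRP")
  d["Complex2"] <- q("k2_plus") * g("Complex1") * g("RcdA") -
    q("k2_minus") * g("Complex2") + q("k3_minus") * g("Complex3") -
    q("k3_plus") * g("cdG")^2 * g("Complex2")
  d["RcdA"] <- q("ks_RcdA") * oracle_hill_a(g("CtrAP"), q("Ja_RcdA_CtrA"), 2) -
    q("kd_RcdA") * g("RcdA") * g("Complex1") / (q("Jd_RcdA") + g("Complex1"))
  d["Complex3"] <- q("k3_plus") * g("cdG")^2 * g("Complex2") -
    q("k3_minus") * g("Complex3")
  d["PleD"] <- q("ks_PleD") * oracle_hill_a(g("CtrAP"), q("Ja_PleD_CtrA"), 2) -
    q("kd_PleD") * g("PleD") - q("kphos_PleD") * g("PleD") +
    q("kdephos_PleD") * PleC * g("PleDP")
  d["PleDP"] <- q("kphos_PleD") * g("PleD") - q("kdephos_PleD") * PleC * g("PleDP")
  d["PdeA"] <- q("ks_PdeA") * oracle_hill_a(g("CtrAP"), q("Ja_PdeA_CtrA"), 2) -
    q("kd_PdeA") * g("PdeA") * g("Complex1") / (q("Jd_PdeA") + g("Complex1"))
  d["cdG"] <- q("ks_cdG") * (1 + q("alpha_PleD") * g("PleD")) *
    oracle_hill_i(g("cdG"), q("Ji_cdG_cdG"), 2) -
    q("kd_cdG") * (1 + q("alpha_PdeA") * g("PdeA")) * g("cdG") +
    q("k3_minus") * g("Complex3") - q("k3_plus") * g("cdG")^2 * g("Complex2")
  d
}

# random valid model state for property tests
random_state <- function() {
  y <- stats::runif(29, 0, 8)
  names(y) <- caulo_state_names()
  y["Ini"] <- stats::runif(1, 0, 0.05)
  y["Elong"] <- stats::runif(1, 0, 1)
  y["Zring"] <- stats::runif(1, 0, 1)
  y[c("hCori", "hccrM", "hctrA")] <- stats::runif(3, 0, 1)
  y["CckAP"] <- stats::runif(1, 0, 0.3)
  y
}

# memoized reference simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}
wt_sim <- function(duration = 1200)
  cached_sim(paste0("wt", duration),
             simulate_caulobacter(duration = duration, out_step = 2))
wt_eval_sim <- function()
  cached_sim("wt_eval",
             simulate_caulobacter(duration = 900, rtol = 1e-6, atol = 1e-8))
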