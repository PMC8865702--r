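# Performance twin of caulo_rhs(): parameters are unpacked once into the
# closure and states are read positionally, which matters because the
# integrator evaluates the RHS tens of thousands of times per run.  Must
# stay term-for-term identical to caulo_rhs(); the test suite asserts
# agreement at random states to 1e-12 relative.
make_rhs <- function(p, qssa = FALSE) {
  e <- list2env(as.list(p))
  e$qssa <- qssa
  with(e, {
    Ja_Ini4 <- Ja_Ini^4; Ji_Ini4 <- Ji_Ini^4; P_elong4 <- P_elong^4
    Jm_Cori4 <- Jm_Cori^4; Jm_ccrM4 <- Jm_ccrM^4; Jm_ctrA4 <- Jm_ctrA^4
    Ja_ccrM_CtrA2 <- Ja_ccrM_CtrA^2; Ji_ccrM_SciP2 <- Ji_ccrM_SciP^2
    Ji_dnaA_GcrA2 <- Ji_dnaA_GcrA^2; Ja_gcrA_DnaA2 <- Ja_gcrA_DnaA^2
    Ji_gcrA_CtrA2 <- Ji_gcrA_CtrA^2; Ja_sciP_CtrA2 <- Ja_sciP_CtrA^2
    Ja_ctrA_GcrA2 <- Ja_ctrA_GcrA^2; Ji_ctrA_CtrA4 <- Ji_ctrA_CtrA^4
    Ji_ctrA_SciP4 <- Ji_ctrA_SciP^4; Ja_ctrA_CtrA2 <- Ja_ctrA_CtrA^2
    Jd_CtrA_ClpXP2 <- Jd_CtrA_ClpXP^2
    Ja_CpdR_CtrA2 <- Ja_CpdR_CtrA^2; Ja_RcdA_CtrA2 <- Ja_RcdA_CtrA^2
    Ja_PleD_CtrA2 <- Ja_PleD_CtrA^2; Ja_PdeA_CtrA2 <- Ja_PdeA_CtrA^2
    Ji_cdG2 <- Ji_cdG_cdG^2

    function(t, y, ks_Zring, plec_t0) {
      if (any(y < 0)) {
        if (any(y < -1e-6))
          stop("negative state in integration: ",
               paste(names(y)[y < -1e-6], collapse = ", "))
        y[y < 0] <- 0
      }
      Ini <- y[[1L]]; Elong <- y[[2L]]
      hCori <- y[[4L]]; hccrM <- y[[5L]]; hctrA <- y[[6L]]
      IccrM <- y[[7L]]; mccrM <- y[[8L]]; mdnaA <- y[[9L]]
      mgcrA <- y[[10L]]; msciP <- y[[11L]]; mctrA <- y[[12L]]
      CcrM <- y[[13L]]; DnaA <- y[[14L]]; GcrA <- y[[15L]]; SciP <- y[[16L]]
      CtrA <- y[[17L]]; CtrAP <- y[[18L]]; CckAP <- y[[19L]]
      Complex1 <- y[[20L]]; CpdR <- y[[21L]]; CpdRP <- y[[22L]]
      Complex2 <- y[[23L]]; RcdA <- y[[24L]]; Complex3 <- y[[25L]]
      PleD <- y[[26L]]; PleDP <- y[[27L]]; PdeA <- y[[28L]]; cdG <- y[[29L]]

      ts <- plec_w * (t - plec_t0)
      PleC <- plec_A1 * sin(ts + plec_phi1) + plec_A2 * sin(ts + plec_phi2)
      if (PleC < 0) PleC <- 0

      CtrAP2 <- CtrAP * CtrAP
      CtrAP4 <- CtrAP2 * CtrAP2
      rD <- (DnaA / Theta_DnaA)^4
      rC <- (CtrAP / Theta_CtrA)^4
      CcrM4 <- CcrM^4
      cdG2 <- cdG * cdG

      dIni <- ks_Ini * rD / (Ja_Ini4 + rC + rD) *
        (1 + 1 / (Ji_Ini4 + (hCori / Theta_Cori)^4))
      El4 <- Elong^4
      dElong <- k_elong * El4 / (El4 + P_elong4)
      dZring <- ks_Zring
      dhCori <- -km_Cori * CcrM4 / (Jm_Cori4 + CcrM4) * hCori
      dhccrM <- -km_ccrM * CcrM4 / (Jm_ccrM4 + CcrM4) * hccrM
      dhctrA <- -km_ctrA * CcrM4 / (Jm_ctrA4 + CcrM4) * hctrA

      dIccrM <- ks_IccrM * (CtrAP2 / (Ja_ccrM_CtrA2 + CtrAP2)) *
        (Ji_ccrM_SciP2 / (Ji_ccrM_SciP2 + SciP * SciP)) * hccrM -
        kd_IccrM * IccrM
      dmccrM <- ks_ccrM * IccrM - kd_ccrM * mccrM
      dmdnaA <- ks_dnaA * (Ji_dnaA_GcrA2 / (Ji_dnaA_GcrA2 + GcrA * GcrA)) *
        (2 - hCori) - kd_dnaA * mdnaA
      dmgcrA <- ks_gcrA * (DnaA * DnaA / (Ja_gcrA_DnaA2 + DnaA * DnaA)) *
        (Ji_gcrA_CtrA2 / (Ji_gcrA_CtrA2 + CtrAP2)) - kd_gcrA * mgcrA
      dmsciP <- ks_sciP * CtrAP2 / (Ja_sciP_CtrA2 + CtrAP2) - kd_sciP * msciP
      SciP4 <- SciP^4
      dmctrA <- ks1_ctrA * (GcrA * GcrA / (Ja_ctrA_GcrA2 + GcrA * GcrA)) *
        (Ji_ctrA_CtrA4 / (Ji_ctrA_CtrA4 + CtrAP4)) *
        (Ji_ctrA_SciP4 / (Ji_ctrA_SciP4 + SciP4)) * hctrA +
        ks2_ctrA * CtrAP2 / (Ja_ctrA_CtrA2 + CtrAP2) - kd_ctrA * mctrA

      dCcrM <- ks_CcrM * mccrM - kd_CcrM * CcrM
      dDnaA <- ks_DnaA * mdnaA - kd_DnaA * DnaA
      dGcrA <- ks_GcrA * mgcrA - kd_GcrA * GcrA
      dSciP <- ks_SciP * msciP - kd_SciP * SciP

      C3 <- if (qssa) k3_plus * cdG2 * Complex2 / k3_minus else Complex3
      degC <- kd_CtrA + kd_CtrA_ClpXP * C3 * C3 / (Jd_CtrA_ClpXP2 + C3 * C3)
      pho <- kpho_CtrA * CckAP * CtrA
      depho <- kdepho_CtrA * CtrAP
      dCtrA <- ks_CtrA * mctrA - degC * CtrA - pho + depho
      dCtrAP <- -degC * CtrAP + pho - depho

      dCckAP <- kpho_CckA * (CckA_T - CckAP) -
        kdepho_CckA * (1 + alpha_cdG * cdG) * CckAP
      c1frac <- Complex1 / (Jd_CpdR + Complex1)
      dComplex1 <- k1_plus * ClpXP * CpdR - k1_minus * Complex1 -
        k2_plus * Complex1 * RcdA + k2_minus * Complex2
      dCpdR <- ks_CpdR * CtrAP2 / (Ja_CpdR_CtrA2 + CtrAP2) -
        kd_CpdR * CpdR * c1frac + k1_minus * Complex1 -
        k1_plus * ClpXP * CpdR + kdephos_CpdR * CpdRP -
        kphos_CpdR * CckAP * CpdR
      dCpdRP <- -kd_CpdR * CpdRP * c1frac +
        kphos_CpdR * CckAP * CpdR - kdephos_CpdR * CpdRP
      dComplex2 <- k2_plus * Complex1 * RcdA - k2_minus * Complex2 +
        (if (qssa) 0 else k3_minus * Complex3 - k3_plus * cdG2 * Complex2)
      dRcdA <- ks_RcdA * CtrAP2 / (Ja_RcdA_CtrA2 + CtrAP2) -
        kd_RcdA * RcdA * Complex1 / (Jd_RcdA + Complex1)
      dComplex3 <- if (qssa) 0 else
        k3_plus * cdG2 * Complex2 - k3_minus * Complex3
      dPleD <- ks_PleD * CtrAP2 / (Ja_PleD_CtrA2 + CtrAP2) -
        kd_PleD * PleD - kphos_PleD * PleD + kdephos_PleD * PleC * PleDP
      dPleDP <- kphos_PleD * PleD - kdephos_PleD * PleC * PleDP
      dPdeA <- ks_PdeA * CtrAP2 / (Ja_PdeA_CtrA2 + CtrAP2) -
        kd_PdeA * PdeA * Complex1 / (Jd_PdeA + Complex1)
      dcdG <- ks_cdG * (1 + alpha_PleD * PleD) * Ji_cdG2 / (Ji_cdG2 + cdG2) -
        kd_cdG * (1 + alpha_PdeA * PdeA) * cdG +
        (if (qssa) 0 else k3_minus * Complex3 - k3_plus * cdG2 * Complex2)

      list(c(dIni, dElong, dZring, dhCori, dhccrM, dhctrA,
             dIccrM, dmccrM, dmdnaA, dmgcrA, dmsciP, dmctrA,
             dCcrM, dDnaA, dGcrA, dSciP, dCtrA, dCtrAP,
             dCckAP, dComplex1, dCpdR, dCpdRP, dComplex2, dRcdA, dComplex3,
             dPleD, dPleDP, dPdeA, dcdG))
    }
  })
}
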