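#' Hill activation and inhibition
#'
#' Elementary regulatory building blocks of the model:
#' \code{hill_activation} returns \eqn{x^n / (J^n + x^n)} and
#' \code{hill_inhibition} its complement \eqn{J^n / (J^n + x^n)}.
#'
#' @param x regulator concentration (a.u.), \code{x >= 0}; vectorised.
#' @param J microscopic dissociation constant, \code{J > 0}.
#' @param n integer Hill exponent, \code{n >= 1}.
#' @return fraction in \code{[0, 1]}.
#' @examples
#' hill_activation(10, 5, 2)   # 0.8
#' hill_inhibition(10, 5, 2)   # 0.2
#' @export
hill_activation <- function(x, J, n) {
  if (any(x < 0)) stop("hill_activation: x must be >= 0")
  if (J <= 0) stop("hill_activation: J must be > 0")
  if (n < 1) stop("hill_activation: n must be >= 1")
  x^n / (J^n + x^n)
}

#' @rdname hill_activation
#' @export
hill_inhibition <- function(x, J, n) {
  if (any(x < 0)) stop("hill_inhibition: x must be >= 0")
  if (J <= 0) stop("hill_inhibition: J must be > 0")
  if (n < 1) stop("hill_inhibition: n must be >= 1")
  J^n / (J^n + x^n)
}

#' PleC phosphatase forcing function
#'
#' PleC, the main phosphatase of PleD, is not a model state; its cell-cycle
#' profile enters as the fixed two-sinusoid forcing
#' \eqn{A_1 \sin(\omega t + \phi_1) + A_2 \sin(\omega t + \phi_2)}
#' fitted to quantified immunoblot data over one cycle.
#'
#' @param t time in minutes (vectorised).
#' @param p a \code{\link{caulo_params}} vector (forcing coefficients
#'   \code{plec_A1}, \code{plec_w}, \code{plec_phi1}, \code{plec_A2},
#'   \code{plec_phi2}).
#' @return PleC level in a.u.
#' @examples
#' plec_level(0)   # about 0.9
#' @export
plec_level <- function(t, p = caulo_params()) {
  p[["plec_A1"]] * sin(p[["plec_w"]] * t + p[["plec_phi1"]]) +
    p[["plec_A2"]] * sin(p[["plec_w"]] * t + p[["plec_phi2"]])
}

#' Model state names
#' @return character vector of the 29 continuous state variables, in
#'   canonical order.
#' @export
caulo_state_names <- function() names(caulo_state())

#' Right-hand side of the cell-cycle ODE system
#'
#' Instantaneous rates of all 29 continuous states: DNA progress variables
#' (\code{Ini}, \code{Elong}, \code{Zring}), hemimethylation probabilities,
#' six mRNAs, the five master regulators (with CtrA split into
#' unphosphorylated and phosphorylated forms), and the protease-complex /
#' c-di-GMP module.  Discrete events are handled by the event engine, not
#' here.
#'
#' @param t time (min).  The PleC forcing is evaluated at
#'   \code{t - plec_t0}.
#' @param y named state vector (see \code{\link{caulo_state}}).
#' @param p parameter vector from \code{\link{caulo_params}}.
#' @param ks_Zring current Z-ring clock rate (0 before replication
#'   initiation, \code{p["ks_Zring_on"]} during replication).
#' @param plec_t0 time origin of the PleC forcing (the birth time of the
#'   current cycle when the forcing is re-zeroed per cycle; 0 for absolute
#'   time).
#' @param qssa logical; if \code{TRUE} Complex 3 is taken at its algebraic
#'   quasi-steady state \eqn{k_3^+ [cdG]^2 [Complex2] / k_3^-} and its
#'   differential equation is dropped.
#' @return named list whose first element is the derivative vector (deSolve
#'   convention).
#' @export
caulo_rhs <- function(t, y, p, ks_Zring = 0, plec_t0 = 0, qssa = FALSE) {
  if (any(!is.finite(y))) stop("caulo_rhs: non-finite state")
  if (any(y < -1e-6)) stop("caulo_rhs: negative state: ",
                           paste(names(y)[y < -1e-6], collapse = ", "))
  y[y < 0] <- 0
  with(as.list(c(y, p)), {
    # phosphatase level: the fitted two-sinusoid profile, truncated at 0
    # (a negative phosphatase concentration would reverse the PleD
    # dephosphorylation flux and destabilise the system)
    PleC <- max(0, plec_A1 * sin(plec_w * (t - plec_t0) + plec_phi1) +
                   plec_A2 * sin(plec_w * (t - plec_t0) + plec_phi2))

    ## -- DNA replication & methylation --
    dIni <- ks_Ini *
      (DnaA / Theta_DnaA)^4 /
        (Ja_Ini^4 + (CtrAP / Theta_CtrA)^4 + (DnaA / Theta_DnaA)^4) *
      (1 + 1 / (Ji_Ini^4 + (hCori / Theta_Cori)^4))
    dElong <- k_elong * Elong^4 / (Elong^4 + P_elong^4)
    dZring <- ks_Zring
    dhCori <- -km_Cori * CcrM^4 / (Jm_Cori^4 + CcrM^4) * hCori
    dhccrM <- -km_ccrM * CcrM^4 / (Jm_ccrM^4 + CcrM^4) * hccrM
    dhctrA <- -km_ctrA * CcrM^4 / (Jm_ctrA^4 + CcrM^4) * hctrA

    ## -- mRNAs --
    dIccrM <- ks_IccrM *
      (CtrAP^2 / (Ja_ccrM_CtrA^2 + CtrAP^2)) *
      (Ji_ccrM_SciP^2 / (Ji_ccrM_SciP^2 + SciP^2)) * hccrM -
      kd_IccrM * IccrM
    dmccrM <- ks_ccrM * IccrM - kd_ccrM * mccrM
    dmdnaA <- ks_dnaA * (Ji_dnaA_GcrA^2 / (Ji_dnaA_GcrA^2 + GcrA^2)) *
      (2 - hCori) - kd_dnaA * mdnaA
    dmgcrA <- ks_gcrA *
      (DnaA^2 / (Ja_gcrA_DnaA^2 + DnaA^2)) *
      (Ji_gcrA_CtrA^2 / (Ji_gcrA_CtrA^2 + CtrAP^2)) -
      kd_gcrA * mgcrA
    dmsciP <- ks_sciP * CtrAP^2 / (Ja_sciP_CtrA^2 + CtrAP^2) - kd_sciP * msciP
    dmctrA <- ks1_ctrA *
      (GcrA^2 / (Ja_ctrA_GcrA^2 + GcrA^2)) *
      (Ji_ctrA_CtrA^4 / (Ji_ctrA_CtrA^4 + CtrAP^4)) *
      (Ji_ctrA_SciP^4 / (Ji_ctrA_SciP^4 + SciP^4)) * hctrA +
      ks2_ctrA * CtrAP^2 / (Ja_ctrA_CtrA^2 + CtrAP^2) -
      kd_ctrA * mctrA

    ## -- master regulator proteins --
    dCcrM <- ks_CcrM * mccrM - kd_CcrM * CcrM
    dDnaA <- ks_DnaA * mdnaA - kd_DnaA * DnaA
    dGcrA <- ks_GcrA * mgcrA - kd_GcrA * GcrA
    dSciP <- ks_SciP * msciP - kd_SciP * SciP

    C3 <- if (qssa) k3_plus * cdG^2 * Complex2 / k3_minus else Complex3
    # ClpXP-mediated cyclic proteolysis saturates in Complex 3; with
    # Jd_CtrA_ClpXP = 0 it degenerates to a constant rate (mutant variant)
    deg_CtrA <- kd_CtrA +
      kd_CtrA_ClpXP * C3^2 / (Jd_CtrA_ClpXP^2 + C3^2)
    dCtrA <- ks_CtrA * mctrA - deg_CtrA * CtrA -
      kpho_CtrA * CckAP * CtrA + kdepho_CtrA * CtrAP
    dCtrAP <- -deg_CtrA * CtrAP +
      kpho_CtrA * CckAP * CtrA - kdepho_CtrA * CtrAP

    ## -- protease complexes & c-di-GMP --
    dCckAP <- kpho_CckA * (CckA_T - CckAP) -
      kdepho_CckA * (1 + alpha_cdG * cdG) * CckAP
    dComplex1 <- k1_plus * ClpXP * CpdR - k1_minus * Complex1 -
      k2_plus * Complex1 * RcdA + k2_minus * Complex2
    dCpdR <- ks_CpdR * CtrAP^2 / (Ja_CpdR_CtrA^2 + CtrAP^2) -
      kd_CpdR * CpdR * Complex1 / (Jd_CpdR + Complex1) +
      k1_minus * Complex1 - k1_plus * ClpXP * CpdR +
      kdephos_CpdR * CpdRP - kphos_CpdR * CckAP * CpdR
    dCpdRP <- -kd_CpdR * CpdRP * Complex1 / (Jd_CpdR + Complex1) +
      kphos_CpdR * CckAP * CpdR - kdephos_CpdR * CpdRP
    dComplex2 <- k2_plus * Complex1 * RcdA - k2_minus * Complex2 +
      (if (qssa) 0 else k3_minus * Complex3 - k3_plus * cdG^2 * Complex2)
    dRcdA <- ks_RcdA * CtrAP^2 / (Ja_RcdA_CtrA^2 + CtrAP^2) -
      kd_RcdA * RcdA * Complex1 / (Jd_RcdA + Complex1)
    dComplex3 <- if (qssa) 0 else k3_plus * cdG^2 * Complex2 - k3_minus * Complex3
    dPleD <- ks_PleD * CtrAP^2 / (Ja_PleD_CtrA^2 + CtrAP^2) -
      kd_PleD * PleD - kphos_PleD * PleD + kdephos_PleD * PleC * PleDP
    dPleDP <- kphos_PleD * PleD - kdephos_PleD * PleC * PleDP
    dPdeA <- ks_PdeA * CtrAP^2 / (Ja_PdeA_CtrA^2 + CtrAP^2) -
      kd_PdeA * PdeA * Complex1 / (Jd_PdeA + Complex1)
    # cdG here is the lumped PopA:2c-di-GMP species, so its exchange with
    # Complex 3 carries the same [cdG]^2 order as complex formation; under
    # QSSA the exchange flux is identically zero
    dcdG <- ks_cdG * (1 + alpha_PleD * PleD) *
      Ji_cdG_cdG^2 / (Ji_cdG_cdG^2 + cdG^2) -
      kd_cdG * (1 + alpha_PdeA * PdeA) * cdG +
      (if (qssa) 0 else k3_minus * Complex3 - k3_plus * cdG^2 * Complex2)

    list(c(dIni, dElong, dZring, dhCori, dhccrM, dhctrA,
           dIccrM, dmccrM, dmdnaA, dmgcrA, dmsciP, dmctrA,
           dCcrM, dDnaA, dGcrA, dSciP, dCtrA, dCtrAP,
           dCckAP, dComplex1, dCpdR, dCpdRP, dComplex2, dRcdA, dComplex3,
           dPleD, dPleDP, dPdeA, dcdG))
  })
}
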