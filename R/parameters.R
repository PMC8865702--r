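#' Kinetic parameter set for the cell-cycle model
#'
#' Returns the full named parameter vector of the model: rate constants
#' (min^-1), dimensionless dissociation/binding constants, scaling constants,
#' the PleC forcing-function coefficients, the Z-ring clock rate and the
#' discrete event thresholds.  Defaults are the published best-fit values.
#' Individual entries can be overridden by name.
#'
#' @param ... named overrides, e.g. \code{caulo_params(ks_ccrM = 0)}.
#' @return a named numeric vector of class \code{caulo_params}.
#' @examples
#' p <- caulo_params()
#' p["ks_Ini"]
#' mut <- caulo_params(ks_dnaA = 0)   # dnaA knockout
#' @export
caulo_params <- function(...) {
  p <- c(
    ## --- DNA replication & methylation ---
    ks_Ini    = 3.104e-4,  # initiation progress rate, min^-1
    k_elong   = 6.53e-3,   # elongation rate, min^-1
    P_elong   = 0.05,      # initiation-complete threshold on Ini
    km_Cori   = 1.5637,    # re-methylation rates of the three tracked loci
    km_ccrM   = 2.2763,
    km_ctrA   = 1.4645,
    Ja_Ini    = 1,
    Ji_Ini    = 1.4565,
    Jm_Cori   = 0.95,
    Jm_ccrM   = 0.95,
    Jm_ctrA   = 0.95,
    Theta_CtrA = 6.0,      # concentration scalings inside the initiation Hill
    Theta_DnaA = 0.5,
    Theta_Cori = 0.308,
    ## --- mRNA synthesis / decay ---
    ks_IccrM  = 0.1105,
    kd_IccrM  = 0.0696,
    ks_ccrM   = 0.2557,
    kd_ccrM   = 0.1005,
    ks_dnaA   = 0.199,
    kd_dnaA   = 0.0693,
    ks_gcrA   = 5.4235,
    kd_gcrA   = 0.7342,
    ks1_ctrA  = 1.0035,    # P1 promoter (GcrA-activated, methylation-gated)
    ks2_ctrA  = 0.0937,    # P2 promoter (CtrA~P autoactivated)
    kd_ctrA   = 0.0983,
    ks_sciP   = 0.583,
    kd_sciP   = 0.0523,
    Ja_ccrM_CtrA = 5,
    Ji_ccrM_SciP = 6,
    Ji_dnaA_GcrA = 3,
    Ja_gcrA_DnaA = 1.25,
    Ji_gcrA_CtrA = 5,
    Ja_ctrA_CtrA = 5,
    Ja_ctrA_GcrA = 3,
    Ji_ctrA_CtrA = 8,
    Ji_ctrA_SciP = 8,
    Ja_sciP_CtrA = 5,
    ## --- master regulator proteins ---
    ks_CcrM   = 0.0834,
    kd_CcrM   = 0.07,
    ks_DnaA   = 0.0787,
    kd_DnaA   = 0.07,
    ks_GcrA   = 0.032,
    kd_GcrA   = 0.022,
    ks_SciP   = 0.1294,
    kd_SciP   = 0.0673,
    ks_CtrA   = 0.0404,
    kd_CtrA   = 0.002,          # basal, Complex-3 independent
    kd_CtrA_ClpXP = 0.053,      # cyclic ClpXP-mediated proteolysis
    Jd_CtrA_ClpXP = 4,
    kpho_CtrA   = 4.2919,
    kdepho_CtrA = 0.113,
    kpho_CckA   = 1.027,
    kdepho_CckA = 0.9242,
    ## --- protease complexes & c-di-GMP module ---
    k1_plus  = 0.6072,   # ClpXP + CpdR            <-> Complex1
    k1_minus = 3.3013,
    k2_plus  = 1.4375,   # Complex1 + RcdA         <-> Complex2
    k2_minus = 0.8164,
    k3_plus  = 170.4913, # Complex2 + cdG (PopA:2cdG) <-> Complex3
    k3_minus = 2.3133,
    kphos_PleD   = 0.046,
    kdephos_PleD = 0.0414,
    ks_CpdR   = 1.2227,
    kd_CpdR   = 1.6152,
    kphos_CpdR   = 1.1239,
    kdephos_CpdR = 1.3854,
    ks_RcdA   = 0.1642,
    kd_RcdA   = 0.2323,
    ks_cdG    = 0.0099,
    kd_cdG    = 0.9893,
    ks_PleD   = 0.0956,
    kd_PleD   = 0.1314,
    ks_PdeA   = 0.012,
    kd_PdeA   = 0.5161,
    Ja_CpdR_CtrA = 15,
    Jd_CpdR      = 6,
    Ja_RcdA_CtrA = 15,
    Jd_RcdA      = 2,
    Ja_PdeA_CtrA = 5,
    Jd_PdeA      = 5,
    Ja_PleD_CtrA = 2.5,
    Ji_cdG_cdG   = 0.2,
    CckA_T    = 0.3,     # total CckA pool (conserved)
    ClpXP     = 1,       # free protease pool, never depleted
    alpha_PdeA = 7,
    alpha_PleD = 1500,
    alpha_cdG  = 10,
    ## --- PleC forcing function: A1*sin(w t + phi1) + A2*sin(w t + phi2) ---
    plec_A1   = 80.09,
    plec_w    = 0.013,   # rad min^-1
    plec_phi1 = 1.74,
    plec_A2   = 78.77,
    plec_phi2 = 4.85,
    ## --- Z-ring clock and event thresholds ---
    ks_Zring_on  = 0.011,  # dZring/dt while replication is under way
    Elong_ccrM   = 0.2,    # fork passes ccrM locus
    Elong_ctrA   = 0.375,  # fork passes ctrA locus
    Elong_term   = 1.0,    # elongation terminates
    Zring_div    = 1.0,    # Z-ring constriction / chromosome separation
    T_target     = 150     # wild-type cycle-period target, min
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- unlist(ov)
  }
  validate_params(p)
  class(p) <- c("caulo_params", "numeric")
  p
}

validate_params <- function(p) {
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (any(p < 0)) stop("negative parameter value: ",
                       paste(names(p)[p < 0], collapse = ", "))
  Js <- grep("^(J|Theta)", names(p), value = TRUE)
  if (any(p[Js] < 0)) stop("dissociation/scaling constants must be >= 0")
  # Jd_* = 0 is a legitimate mutant (constant-rate proteolysis); the other
  # J and Theta constants must stay strictly positive.
  strict <- setdiff(Js, c("Jd_CtrA_ClpXP", "Jd_CpdR", "Jd_RcdA"))
  if (any(p[strict] <= 0)) stop("J/Theta constant must be > 0: ",
                                paste(strict[p[strict] <= 0], collapse = ", "))
  if (p["CckA_T"] <= 0) stop("CckA_T must be > 0")
  invisible(p)
}

#' @export
print.caulo_params <- function(x, ...) {
  cat("<caulo_params> ", length(x), " constants\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Initial cell state (newborn swarmer)
#'
#' The continuous model state at birth of a swarmer cell, plus the discrete
#' bookkeeping quantities (relative DNA content, chromosome count, current
#' Z-ring clock rate) carried alongside the ODE states.
#'
#' Species naming: mRNAs carry an \code{m} prefix (\code{mccrM}, \code{mdnaA},
#' \code{mgcrA}, \code{msciP}, \code{mctrA}); proteins use the capitalised
#' gene name; \code{CtrAP}, \code{CpdRP}, \code{PleDP} and \code{CckAP} are
#' the phosphorylated forms.
#'
#' @param ... named overrides of individual state entries.
#' @return named numeric vector of class \code{caulo_state} (29 continuous
#'   states) with attributes \code{DNA}, \code{Count} and \code{ks_Zring}.
#' @examples
#' s <- caulo_state()
#' s["CtrAP"]
#' @export
caulo_state <- function(...) {
  y <- c(
    Ini = 0.0383, Elong = 0, Zring = 0,
    hCori = 0, hccrM = 0, hctrA = 0,
    IccrM = 0,              # delay intermediate; not tabulated, start empty
    mccrM = 0.173, mdnaA = 3.154, mgcrA = 4.525, msciP = 6.335, mctrA = 0.658,
    CcrM = 0.435, DnaA = 2.638, GcrA = 3.841, SciP = 12.485,
    CtrA = 1.973, CtrAP = 3.960,
    CckAP = 0.042,
    Complex1 = 0.211, CpdR = 1.045, CpdRP = 0.042,
    Complex2 = 0.187, RcdA = 0.789, Complex3 = 3.407,
    PleD = 0.526, PleDP = 0.663, PdeA = 0.228, cdG = 0.511
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(y))
    if (length(bad)) stop("unknown state variable(s): ",
                          paste(bad, collapse = ", "))
    y[names(ov)] <- unlist(ov)
  }
  if (any(!is.finite(y)) || any(y < 0)) stop("state values must be finite and >= 0")
  structure(y, DNA = 1, Count = 1, ks_Zring = 0,
            class = c("caulo_state", "numeric"))
}

#' @export
print.caulo_state <- function(x, ...) {
  cat("<caulo_state>  DNA=", attr(x, "DNA"), " Count=", attr(x, "Count"),
      " ks_Zring=", attr(x, "ks_Zring"), "\n", sep = "")
  print(unclass(structure(as.numeric(x), names = names(x))), ...)
  invisible(x)
}

#' Read / write a parameter set as a flat key-value file
#'
#' The on-disk format is two tab-separated columns (name, value), one
#' parameter per line, \code{#} comments allowed.  The packaged default
#' (\code{system.file("extdata", "params_wildtype.tsv", package =
#' "caulocycle")}) reproduces the published wild-type values exactly.
#'
#' @param path file path.
#' @return \code{read_params}: a \code{caulo_params} vector.
#' @export
read_params <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("name", "value"),
                           comment.char = "#", stringsAsFactors = FALSE)
  do.call(caulo_params, as.list(stats::setNames(tab$value, tab$name)))
}

#' @rdname read_params
#' @param p a \code{caulo_params} vector.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "caulo_params"))
  utils::write.table(
    data.frame(name = names(p), value = format(as.numeric(p), digits = 15)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an initial state as a flat key-value file
#' @param path file path.
#' @return \code{read_state}: a \code{caulo_state} vector.
#' @export
read_state <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("name", "value"),
                           comment.char = "#", stringsAsFactors = FALSE)
  do.call(caulo_state, as.list(stats::setNames(tab$value, tab$name)))
}

#' @rdname read_state
#' @param s a \code{caulo_state} vector.
#' @export
write_state <- function(s, path) {
  stopifnot(inherits(s, "caulo_state"))
  utils::write.table(
    data.frame(name = names(s), value = format(as.numeric(s), digits = 15)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
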