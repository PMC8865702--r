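#' Built-in mutant panel
#'
#' The simulated strain collection: seven genetic strains (knockouts set
#' the corresponding synthesis rate to zero; the non-proteolyzable CtrA
#' allele reduces the cyclic proteolysis rate to 10\%) plus the four
#' proteolysis variants in which a saturable (Michaelis-type) degradation
#' term is made constant-rate by zeroing its half-saturation constant.
#'
#' @return named list of mutant specs; each has \code{name},
#'   \code{overrides} (parameter := value), \code{expected} phenotype class
#'   and a free-text \code{note}.
#' @examples
#' names(builtin_panel())
#' @export
builtin_panel <- function() {
  wt <- caulo_params()
  spec <- function(name, overrides, expected, note)
    list(name = name, overrides = overrides, expected = expected, note = note)
  list(
    dccrM = spec("dccrM", list(ks_ccrM = 0), "oscillatory",
                 "no remethylation; hemimethylation persists; ~164 min cycle"),
    dgcrA = spec("dgcrA", list(ks_gcrA = 0), "oscillatory",
                 "cycle ~10 min longer than wild type"),
    ddnaA = spec("ddnaA", list(ks_dnaA = 0), "arrested",
                 "no initiator; replication never re-initiates"),
    ctrAD3O = spec("ctrAD3O",
                   list(kd_CtrA_ClpXP = unname(0.1 * wt[["kd_CtrA_ClpXP"]])),
                   "oscillatory",
                   "non-proteolyzable CtrA allele: higher, flatter CtrA"),
    cdG0 = spec("cdG0", list(ks_cdG = 0), "oscillatory",
                "no c-di-GMP: CtrA rises with less fluctuation"),
    dpdeA = spec("dpdeA", list(ks_PdeA = 0), "oscillatory",
                 "no hydrolase: higher mean cdG"),
    dpleD = spec("dpleD", list(ks_PleD = 0), "oscillatory",
                 "no cyclase: lower mean cdG"),
    JdCtrA0 = spec("JdCtrA0", list(Jd_CtrA_ClpXP = 0), "defective",
                   "constant-rate CtrA proteolysis: longer cycle, reduced CtrA/SciP amplitude"),
    JdCpdR0 = spec("JdCpdR0", list(Jd_CpdR = 0), "defective",
                   "constant-rate CpdR proteolysis: CtrA oscillation nearly abolished"),
    JdRcdA0 = spec("JdRcdA0", list(Jd_RcdA = 0), "defective",
                   "constant-rate RcdA proteolysis: CtrA oscillation nearly abolished"),
    JdAll0 = spec("JdAll0",
                  list(Jd_CtrA_ClpXP = 0, Jd_CpdR = 0, Jd_RcdA = 0),
                  "defective",
                  "all three cyclic proteolysis terms constant; resembles JdCtrA0")
  )
}

#' Apply a mutant spec to a parameter set
#'
#' @param p wild-type \code{\link{caulo_params}}.
#' @param spec a mutant spec from \code{\link{builtin_panel}}, a mutant
#'   name, or a named list of overrides.
#' @return a new \code{caulo_params}; only the overridden entries differ.
#' @examples
#' mut <- apply_mutant(caulo_params(), "dccrM")
#' @export
apply_mutant <- function(p = caulo_params(), spec) {
  if (is.character(spec)) {
    panel <- builtin_panel()
    if (!spec %in% names(panel))
      stop("unknown mutant '", spec, "'; built-in panel: ",
           paste(names(panel), collapse = ", "))
    spec <- panel[[spec]]
  }
  overrides <- if (!is.null(spec$overrides)) spec$overrides else spec
  bad <- setdiff(names(overrides), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  q <- p
  q[names(overrides)] <- unlist(overrides)
  validate_params(q)
  class(q) <- class(p)
  q
}

#' Simulate and classify the mutant panel
#'
#' Runs wild type plus every panel mutant from the same initial state and
#' summarizes phenotype class, period, mean cdG and total-CtrA amplitude
#' (settled window), with amplitudes relative to wild type.
#'
#' @param panel list of specs (default \code{\link{builtin_panel}}).
#' @param params wild-type parameters.
#' @param duration per-strain simulated minutes (>= 600).
#' @param ... further arguments to \code{\link{simulate_caulobacter}}.
#' @return data.frame, one row per strain (wild type first) with class
#'   \code{caulo_panel}; attribute \code{sims} holds the trajectories.
#' @export
run_mutant_panel <- function(panel = builtin_panel(),
                             params = caulo_params(),
                             duration = 1200, ...) {
  strains <- c(list(wildtype = list(name = "wildtype", overrides = list(),
                                    expected = "oscillatory", note = "")),
               panel)
  sims <- lapply(strains, function(s)
    simulate_caulobacter(apply_mutant(params, s$overrides), duration = duration,
                         out_step = 2, ...))
  settle <- function(sim) sim$time > max(sim$time) - 310
  row <- function(s, sim) {
    m <- cycle_metrics(sim)
    sel <- settle(sim)
    ct <- species_series(sim, "CtrA")[sel, 1]
    data.frame(strain = s$name, expected = s$expected,
               phenotype = m$phenotype, period = m$period,
               n_initiations = m$n_initiations,
               mean_cdG = mean(sim$state[sel, "cdG"]),
               ctrA_amplitude = diff(range(ct)),
               sciP_amplitude = diff(range(sim$state[sel, "SciP"])),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(row, strains, sims))
  out$ctrA_amp_rel_wt <- out$ctrA_amplitude / out$ctrA_amplitude[1]
  rownames(out) <- NULL
  structure(out, sims = sims, class = c("caulo_panel", "data.frame"))
}

#' @export
print.caulo_panel <- function(x, ...) {
  cat("Mutant panel (", nrow(x) - 1, " strains + wild type)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
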