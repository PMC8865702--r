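#' Cell-cycle period from a simulation
#'
#' The period is the mean interval between successive reference events
#' (replication initiation by default) after discarding transient cycles.
#' With fewer than three reference events the oscillation is classed as
#' arrested and the period is \code{NA}.
#'
#' @param sim a \code{caulo_sim}.
#' @param ref_event reference event id (\code{"initiation"} or
#'   \code{"zring"}; both give the same period once settled).
#' @param transient number of leading inter-event intervals discarded as
#'   transient (default 2, capped so at least one interval remains).
#' @return list with \code{period} (min, \code{NA} if arrested),
#'   \code{intervals} (the settled intervals used), \code{converged}
#'   (successive settled intervals within 1\%), \code{n_events}.
#' @examples
#' \donttest{
#' cycle_period(simulate_caulobacter(duration = 700))$period  # about 150
#' }
#' @export
cycle_period <- function(sim, ref_event = "initiation", transient = 2) {
  ev <- sim$events$time[sim$events$event == ref_event]
  if (length(ev) < 3)
    return(list(period = NA_real_, intervals = numeric(),
                converged = FALSE, n_events = length(ev)))
  iv <- diff(ev)
  drop <- min(transient, length(iv) - 1L)
  settled <- iv[seq.int(drop + 1L, length(iv))]
  period <- mean(settled)
  converged <- length(settled) < 2 ||
    all(abs(diff(settled)) / period < 0.01)
  list(period = period, intervals = settled, converged = converged,
       n_events = length(ev))
}

#' S-phase duration (initiation to Z-ring constriction)
#'
#' With a constant Z-ring clock rate \eqn{k_{s,Zring}} the interval is
#' analytically \eqn{1/k_{s,Zring} \approx 90.9} min; this measures it from
#' the event log of the last complete initiation/Z-ring pair.
#'
#' @param sim a \code{caulo_sim}.
#' @return minutes, or \code{NA} (with a \code{"status"} attribute) if no
#'   complete pair exists.
#' @export
sphase_interval <- function(sim) {
  ini <- sim$events$time[sim$events$event == "initiation"]
  zr <- sim$events$time[sim$events$event == "zring"]
  if (!length(ini) || !length(zr))
    return(structure(NA_real_, status = "no complete initiation/zring pair"))
  z <- max(zr)
  i <- ini[ini < z]
  if (!length(i))
    return(structure(NA_real_, status = "no initiation before last zring"))
  z - max(i)
}

#' Phenotype classification and per-cycle metrics
#'
#' Classifies a trajectory as \code{"oscillatory"}, \code{"arrested"}
#' (fewer than 3 replication initiations) or \code{"damped"} (total-CtrA
#' oscillation amplitude in the last cycle below 10\% of its first-cycle
#' amplitude), and collects cycle metrics: period, S-phase duration, and
#' per-species min/max/amplitude over the last settled cycle.
#'
#' @param sim a \code{caulo_sim}, at least several hundred minutes long.
#' @return object of class \code{caulo_metrics}.
#' @export
cycle_metrics <- function(sim) {
  per <- cycle_period(sim)
  ini <- sim$events$time[sim$events$event == "initiation"]
  ctra <- species_series(sim, "CtrA")[, 1]
  phen <- if (per$n_events < 3) "arrested" else {
    amp_cycle <- function(t1, t2) {
      sel <- sim$time >= t1 & sim$time <= t2
      diff(range(ctra[sel]))
    }
    # reference amplitude is the first post-transient cycle: comparing
    # against the literal first cycle would misread the relaxation of the
    # initial condition as damping
    k <- min(3L, length(ini) - 1L)
    ref <- amp_cycle(ini[k], ini[k + 1])
    last <- amp_cycle(ini[length(ini) - 1], ini[length(ini)])
    if (last < 0.1 * ref) "damped" else "oscillatory"
  }
  amps <- NULL
  if (per$n_events >= 2) {
    t1 <- ini[length(ini) - 1]; t2 <- ini[length(ini)]
    sel <- sim$time >= t1 & sim$time <= t2
    sub <- sim$state[sel, setdiff(colnames(sim$state),
                                  c("DNA", "Count", "ks_Zring")), drop = FALSE]
    amps <- data.frame(species = colnames(sub),
                       min = apply(sub, 2, min),
                       max = apply(sub, 2, max))
    amps$amplitude <- amps$max - amps$min
    rownames(amps) <- NULL
  }
  structure(list(phenotype = phen, period = per$period,
                 period_converged = per$converged,
                 n_initiations = per$n_events,
                 sphase = sphase_interval(sim),
                 amplitudes = amps),
            class = "caulo_metrics")
}

#' @rdname cycle_metrics
#' @export
classify_phenotype <- function(sim) cycle_metrics(sim)

#' @export
print.caulo_metrics <- function(x, ...) {
  cat("Cell-cycle metrics\n")
  cat("  phenotype:   ", x$phenotype, "\n", sep = "")
  cat("  period:      ",
      if (is.na(x$period)) "undefined (arrested)"
      else paste0(format(x$period, digits = 6), " min",
                  if (!x$period_converged) " (not converged)"),
      "\n", sep = "")
  cat("  S phase:     ",
      if (is.na(x$sphase)) attr(x$sphase, "status")
      else paste0(format(x$sphase, digits = 5), " min"), "\n", sep = "")
  cat("  initiations: ", x$n_initiations, "\n", sep = "")
  if (!is.null(x$amplitudes)) {
    key <- x$amplitudes[x$amplitudes$species %in%
                          c("CtrA", "CtrAP", "CcrM", "DnaA", "GcrA", "SciP",
                            "cdG"), ]
    cat("  amplitudes over last cycle (key species):\n")
    print(key, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
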