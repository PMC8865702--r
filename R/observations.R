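#' Min-max normalization to the unit interval
#'
#' Affine map sending the minimum of a series to 0 and its maximum to 1,
#' the first step in putting heterogeneous experimental time courses
#' (immunoblot densitometry, microarray signal) on a common scale.
#'
#' @param values numeric vector, length >= 2, not all equal.
#' @return vector of the same length in \code{[0, 1]}.
#' @examples
#' normalize_unit_interval(c(2, 4, 6))   # 0 0.5 1
#' @export
normalize_unit_interval <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  r <- range(values)
  if (r[1] == r[2]) stop("constant series cannot be min-max normalized")
  (values - r[1]) / (r[2] - r[1])
}

#' Rescale normalized values onto a simulation concentration range
#'
#' @param z values in \code{[0, 1]} (see
#'   \code{\link{normalize_unit_interval}}).
#' @param range length-2 numeric \code{c(lo, hi)} with \code{hi > lo >= 0},
#'   the species' targeted range in simulation units.
#' @return \code{lo + z * (hi - lo)}.
#' @examples
#' rescale_to_simulation(c(0, 1), c(2, 8))   # 2 8
#' @export
rescale_to_simulation <- function(z, range) {
  if (length(range) != 2 || range[2] <= range[1] || range[1] < 0)
    stop("range must be c(lo, hi) with hi > lo >= 0")
  range[1] + z * (range[2] - range[1])
}

#' The fifteen observable species used for fitting
#'
#' Five mRNAs, the five master regulator proteins and five proteolysis
#' module proteins.  Protein observables are immunoblot-style totals:
#' \code{CtrA}, \code{CpdR} and \code{PleD} include their phosphorylated
#' forms.
#' @return character vector of species names.
#' @export
fit_species <- function() {
  c("mccrM", "mdnaA", "mgcrA", "msciP", "mctrA",
    "CcrM", "DnaA", "GcrA", "SciP", "CtrA",
    "CpdR", "RcdA", "PleD", "PdeA", "cdG")
}

#' Per-species concentration ranges of a settled cycle
#'
#' The min/max of each observable over the last full cycle of a simulation;
#' used as the targeted scaling ranges when mapping normalized observations
#' onto simulation units.
#'
#' @param sim a settled \code{caulo_sim} (>= 2 initiation events).
#' @param species observables (default \code{\link{fit_species}}).
#' @return data.frame with \code{species}, \code{lo}, \code{hi}.
#' @export
species_ranges <- function(sim, species = fit_species()) {
  ini <- sim$events$time[sim$events$event == "initiation"]
  if (length(ini) >= 2) {
    sel <- sim$time >= ini[length(ini) - 1] & sim$time <= ini[length(ini)]
  } else sel <- rep(TRUE, length(sim$time))
  mat <- species_series(sim, species)[sel, , drop = FALSE]
  data.frame(species = species,
             lo = apply(mat, 2, min), hi = apply(mat, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a synthetic observation set from a trajectory
#'
#' Emulates the sparse, noisy, min-max-normalized time courses digitized
#' from published immunoblots and transcript measurements: each species is
#' sampled at a handful of times over one cycle, corrupted with additive
#' Gaussian noise proportional to its amplitude (truncated at 0), min-max
#' normalized, and tagged with the trajectory's own concentration range for
#' rescaling.  Fully reproducible from \code{seed}.
#'
#' @param sim a settled \code{caulo_sim} covering at least one full cycle.
#' @param species observables to sample (default all 15 fit species).
#' @param n_points sampling times per species, drawn uniformly on
#'   \code{[0, window]} (default 10, matching the 5--15 points per species
#'   of typical published time courses).
#' @param noise_sd noise standard deviation as a fraction of the species'
#'   amplitude over the sampled cycle (default 0.1).
#' @param seed integer RNG seed.
#' @param window observation window in minutes (default 150, one cycle).
#' @return a \code{caulo_obs} data.frame with columns \code{species},
#'   \code{time_min}, \code{raw}, \code{z}, \code{value}, \code{lo},
#'   \code{hi} and attribute \code{source = "synthetic"}.  \code{value} is
#'   \code{z} rescaled to \code{[lo, hi]}.
#' @export
generate_observations <- function(sim, species = fit_species(),
                                  n_points = 10, noise_sd = 0.1, seed = 1,
                                  window = 150) {
  ini <- sim$events$time[sim$events$event == "initiation"]
  if (length(ini) < 2)
    stop("trajectory must cover at least one settled cycle")
  # sample the last full cycle, re-parameterized to [0, window]
  t0 <- ini[length(ini) - 1]
  span <- ini[length(ini)] - t0
  bad <- setdiff(species, c(colnames(sim$state), "CtrA", "CpdR", "PleD"))
  if (length(bad)) stop("species absent from trajectory: ",
                        paste(bad, collapse = ", "))
  mat <- species_series(sim, species)
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_along(species), function(i) {
    tt <- sort(stats::runif(n_points, 0, window))
    sim_t <- t0 + tt / window * span
    v <- stats::approx(sim$time, mat[, i], xout = sim_t, rule = 2, ties = "ordered")$y
    amp <- diff(range(mat[sim$time >= t0 & sim$time <= t0 + span, i]))
    raw <- pmax(0, v + stats::rnorm(n_points, 0, noise_sd * amp))
    # normalization metadata: the sampled range plays the role of the
    # species' targeted simulation range, so rescale(normalize(raw)) == raw
    # and a noiseless fixture is interpolated exactly by its own generator
    lo <- min(raw); hi <- max(raw)
    z <- if (hi > lo) normalize_unit_interval(raw) else rep(0.5, n_points)
    data.frame(species = species[i], time_min = tt, raw = raw, z = z,
               lo = lo, hi = hi, value = raw, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, source = "synthetic", class = c("caulo_obs", "data.frame"))
}

#' Rescale an observation set onto new species ranges
#'
#' Maps the normalized column \code{z} of an observation table onto the
#' per-species ranges of a reference simulation (typically the settled wild
#' type), refreshing \code{lo}, \code{hi} and \code{value}.  This is how
#' externally digitized, unit-less time courses are put on the model's
#' concentration scale before computing the trajectory misfit.
#'
#' @param obs a \code{caulo_obs} table.
#' @param ranges data.frame with \code{species}, \code{lo}, \code{hi}
#'   (see \code{\link{species_ranges}}).
#' @return the rescaled \code{caulo_obs}.
#' @export
rescale_observations <- function(obs, ranges) {
  miss <- setdiff(unique(obs$species), ranges$species)
  if (length(miss)) stop("no range for species: ", paste(miss, collapse = ", "))
  i <- match(obs$species, ranges$species)
  obs$lo <- ranges$lo[i]
  obs$hi <- ranges$hi[i]
  obs$value <- mapply(function(z, lo, hi) rescale_to_simulation(z, c(lo, hi)),
                      obs$z, obs$lo, obs$hi)
  obs
}

#' Read / write observation sets
#'
#' Tab-separated round-trip of a \code{caulo_obs} table (species, time_min,
#' raw, z, lo, hi, value).
#' @param path file path.
#' @return \code{read_observations}: a \code{caulo_obs} data.frame.
#' @export
read_observations <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("species", "time_min", "z", "lo", "hi", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("observation file lacks columns: ",
                         paste(miss, collapse = ", "))
  structure(tab, class = c("caulo_obs", "data.frame"))
}

#' @rdname read_observations
#' @param obs a \code{caulo_obs} table.
#' @export
write_observations <- function(obs, path) {
  utils::write.table(as.data.frame(obs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.caulo_obs <- function(x, ...) {
  cat("<caulo_obs> ", length(unique(x$species)), " species, ",
      nrow(x), " points",
      if (!is.null(attr(x, "source"))) paste0(" [", attr(x, "source"), "]"),
      "\n", sep = "")
  NextMethod()
}
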