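#' The 47-parameter search box for model calibration
#'
#' Lower/upper bounds and starting values for the 47 rate constants chosen
#' for estimation (synthesis/degradation/phosphotransfer rates; most
#' dissociation constants stay fixed).
#'
#' @return data.frame with columns \code{name}, \code{lower}, \code{upper},
#'   \code{start}; 47 rows.
#' @export
search_box <- function() {
  b <- rbind(
    c("km_Cori",       0.35,     5.6,    1.4),
    c("km_ccrM",       0.35,     5.6,    1.4),
    c("km_ctrA",       0.35,     5.6,    1.4),
    c("ks_IccrM",      0.025,    0.4,    0.1),
    c("kd_IccrM",      0.016675, 0.2668, 0.0667),
    c("ks_ccrM",       0.064,    1.024,  0.256),
    c("kd_ccrM",       0.02,     0.32,   0.08),
    c("ks_dnaA",       0.0605,   0.968,  0.242),
    c("kd_dnaA",       0.015,    0.24,   0.06),
    c("ks_gcrA",       1.4,      22.4,   5.6),
    c("kd_gcrA",       0.15,     2.4,    0.6),
    c("ks_sciP",       0.125,    2,      0.5),
    c("kd_sciP",       0.01,     0.16,   0.04),
    c("ks1_ctrA",      0.2475,   3.96,   0.99),
    c("ks2_ctrA",      0.0225,   0.36,   0.09),
    c("kd_ctrA",       0.02075,  0.332,  0.083),
    c("ks_DnaA",       0.01625,  0.26,   0.065),
    c("ks_GcrA",       0.007,    0.112,  0.028),
    c("ks_CcrM",       0.02125,  0.34,   0.085),
    c("ks_SciP",       0.0295,   0.472,  0.1183),
    c("kd_SciP",       0.015,    0.24,   0.06),
    c("ks_CtrA",       0.0108,   0.1728, 0.0432),
    c("kd_CtrA_ClpXP", 0.015,    0.24,   0.06),
    c("k1_plus",       0.15,     2.4,    0.6),
    c("k1_minus",      0.75,     12,     3),
    c("ks_CpdR",       0.175,    2.8,    0.7),
    c("kd_CpdR",       0.375,    6,      1.5),
    c("kdephos_CpdR",  0.25,     4,      1),
    c("kphos_CpdR",    0.25,     4,      1),
    c("k2_plus",       0.275,    4.4,    1.1),
    c("k2_minus",      0.25,     4,      1),
    c("ks_RcdA",       0.0375,   0.6,    0.15),
    c("kd_RcdA",       0.05,     0.8,    0.2),
    c("k3_plus",       35,       560,    140),
    c("k3_minus",      0.5,      8,      2),
    c("ks_cdG",        0.0025,   0.04,   0.01),
    c("kd_cdG",        0.25,     4,      1),
    c("ks_PleD",       0.025,    0.4,    0.1),
    c("kd_PleD",       0.0375,   0.6,    0.15),
    c("kphos_PleD",    0.01,     0.16,   0.04),
    c("kdephos_PleD",  0.01,     0.16,   0.04),
    c("ks_PdeA",       0.0025,   0.04,   0.01),
    c("kd_PdeA",       0.125,    2,      0.5),
    c("kpho_CtrA",     1.25,     20,     5),
    c("kdepho_CckA",   0.25,     4,      1),
    c("kdepho_CtrA",   0.025,    0.4,    0.1),
    c("kpho_CckA",     0.25,     4,      1)
  )
  out <- data.frame(name = b[, 1],
                    lower = as.numeric(b[, 2]),
                    upper = as.numeric(b[, 3]),
                    start = as.numeric(b[, 4]),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$lower < out$upper),
            all(out$start >= out$lower & out$start <= out$upper),
            all(out$name %in% names(caulo_params())))
  out
}

# large finite sentinel: failed / arrested evaluations stay comparable
# inside the evolutionary search without poisoning it with Inf
OBJ_SENTINEL <- 1e6

#' Evaluate both calibration objectives with one simulation
#'
#' f1 is the mean squared deviation between the simulated settled cycle and
#' an observation set (per-species mean of squared residuals, then mean
#' over species); f2 is the absolute deviation of the cycle period from its
#' 150-min target.  Arrested or failed simulations receive a large finite
#' sentinel (1e6) for both objectives.
#'
#' @param x named numeric vector of parameter overrides (a point in the
#'   search box), or \code{NULL} to evaluate \code{fixed} itself.
#' @param obs a \code{caulo_obs} observation table (see
#'   \code{\link{generate_observations}}); required for f1.
#' @param fixed full \code{\link{caulo_params}} supplying every parameter
#'   not in \code{x}.
#' @param eval_duration simulation length per evaluation (min); must cover
#'   >= 3 cycles so one settled cycle can be measured.
#' @param weighting \code{"per_species"} (mean residual per species, then
#'   mean over species: species with fewer points are not down-weighted) or
#'   \code{"pooled"} (grand mean over all residuals).
#' @param window observation window (min), the cycle is mapped onto
#'   \code{[0, window]}.
#' @param rtol,atol integration tolerances for objective evaluations
#'   (looser than simulation defaults; the objectives are smooth at this
#'   resolution and the search needs thousands of evaluations).
#' @return named numeric \code{c(f1, f2)}.
#' @export
evaluate_objectives <- function(x = NULL, obs, fixed = caulo_params(),
                                eval_duration = 900,
                                weighting = c("per_species", "pooled"),
                                window = 150, rtol = 1e-6, atol = 1e-8) {
  weighting <- match.arg(weighting)
  p <- fixed
  if (!is.null(x)) {
    bad <- setdiff(names(x), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(x)] <- x
  }
  sim <- tryCatch(
    simulate_caulobacter(p, duration = eval_duration, rtol = rtol, atol = atol),
    error = function(e) NULL)
  if (is.null(sim))
    return(c(f1 = OBJ_SENTINEL, f2 = OBJ_SENTINEL))
  per <- cycle_period(sim)
  f2 <- if (is.na(per$period)) OBJ_SENTINEL else
    abs(per$period - p[["T_target"]])
  ini <- sim$events$time[sim$events$event == "initiation"]
  if (length(ini) < 2)
    return(c(f1 = OBJ_SENTINEL, f2 = f2))
  t0 <- ini[length(ini) - 1]
  span <- ini[length(ini)] - t0
  sq <- vapply(split(seq_len(nrow(obs)), obs$species), function(idx) {
    sp <- obs$species[idx[1]]
    series <- species_series(sim, sp)[, 1]
    sim_t <- t0 + obs$time_min[idx] / window * span
    v <- stats::approx(sim$time, series, xout = sim_t, rule = 2, ties = "ordered")$y
    res2 <- (v - obs$value[idx])^2
    if (weighting == "per_species") mean(res2) else sum(res2)
  }, numeric(1))
  f1 <- if (weighting == "per_species") mean(sq) else sum(sq) / nrow(obs)
  c(f1 = unname(f1), f2 = unname(f2))
}

#' Trajectory-misfit objective f1
#' @inheritParams evaluate_objectives
#' @param ... passed to \code{\link{evaluate_objectives}}.
#' @return non-negative scalar.
#' @export
objective_f1 <- function(x = NULL, obs, fixed = caulo_params(), ...)
  evaluate_objectives(x, obs, fixed, ...)[["f1"]]

#' Cycle-period objective f2 = |T_c - 150|
#' @inheritParams evaluate_objectives
#' @param ... passed to \code{\link{evaluate_objectives}}.
#' @return non-negative scalar, minutes.
#' @export
objective_f2 <- function(x = NULL, fixed = caulo_params(), ...) {
  p <- fixed
  if (!is.null(x)) p[names(x)] <- x
  sim <- tryCatch(
    simulate_caulobacter(p, duration = 900, rtol = 1e-6, atol = 1e-8),
    error = function(e) NULL)
  if (is.null(sim)) return(OBJ_SENTINEL)
  per <- cycle_period(sim)
  if (is.na(per$period)) OBJ_SENTINEL else abs(per$period - p[["T_target"]])
}

#' Nondominated (Pareto) filter for two minimization objectives
#'
#' @param points data.frame or matrix with columns \code{f1}, \code{f2}
#'   (extra columns are carried through).
#' @return the nondominated subset, ordered by \code{f1} (stable).
#' @examples
#' nondominated_filter(data.frame(f1 = c(1, 2, 2), f2 = c(2, 1, 2)))
#' @export
nondominated_filter <- function(points) {
  pts <- as.data.frame(points)
  stopifnot(all(c("f1", "f2") %in% names(pts)))
  if (!nrow(pts)) return(pts)
  f1 <- pts$f1; f2 <- pts$f2
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    dominated <- (f1 <= f1[i] & f2 <= f2[i]) & (f1 < f1[i] | f2 < f2[i])
    !any(dominated)
  }, logical(1))
  out <- pts[keep, , drop = FALSE]
  out[order(out$f1, out$f2), , drop = FALSE]
}

#' Dominated hypervolume of a 2-D minimization front
#' @param front data.frame with \code{f1}, \code{f2} (need not be filtered).
#' @param ref reference point \code{c(r1, r2)}, worse than every member.
#' @return area dominated by the front within the reference box.
#' @export
hypervolume2d <- function(front, ref) {
  nd <- nondominated_filter(front)
  nd <- nd[nd$f1 < ref[1] & nd$f2 < ref[2], , drop = FALSE]
  if (!nrow(nd)) return(0)
  f1 <- c(nd$f1, ref[1])
  sum((f1[-1] - f1[-length(f1)]) * (ref[2] - nd$f2))
}

# ---- NSGA-II internals ------------------------------------------------

# fast nondominated sorting; returns integer rank (1 = best front)
nds_rank <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  dom_count <- integer(n)
  dominates <- function(i, j)
    all(F[i, ] <= F[j, ]) && any(F[i, ] < F[j, ])
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) dominated_by[[i]] <- c(dominated_by[[i]], j)
      else if (dominates(j, i)) dom_count[i] <- dom_count[i] + 1L
    }
  }
  front <- which(dom_count == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer()
    for (i in front) for (j in dominated_by[[i]]) {
      dom_count[j] <- dom_count[j] - 1L
      if (dom_count[j] == 0L) nxt <- c(nxt, j)
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}

crowding_distance <- function(F) {
  n <- nrow(F)
  d <- numeric(n)
  for (m in seq_len(ncol(F))) {
    o <- order(F[, m])
    rng <- F[o[n], m] - F[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / rng
  }
  d
}

sbx_crossover <- function(a, b, lower, upper, eta = 15, pc = 0.9) {
  p <- length(a)
  if (stats::runif(1) > pc) return(rbind(a, b))
  u <- stats::runif(p)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  cross <- stats::runif(p) < 0.5
  beta[!cross] <- 1
  c1 <- 0.5 * ((1 + beta) * a + (1 - beta) * b)
  c2 <- 0.5 * ((1 - beta) * a + (1 + beta) * b)
  rbind(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutate <- function(x, lower, upper, eta = 20, pm = NULL) {
  p <- length(x)
  if (is.null(pm)) pm <- 1 / p
  mut <- stats::runif(p) < pm
  if (any(mut)) {
    u <- stats::runif(sum(mut))
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta + 1)))
    x[mut] <- x[mut] + delta * (upper[mut] - lower[mut])
  }
  pmin(pmax(x, lower), upper)
}

#' Two-objective parameter search (elitist nondominated sorting GA)
#'
#' Minimizes \code{(f1, f2)} over a box-constrained parameter space with a
#' real-coded NSGA-II: simulated binary crossover, polynomial mutation,
#' binary tournament on (rank, crowding distance), elitist
#' parent-plus-offspring selection, and a cumulative nondominated archive.
#' The archive hypervolume (fixed reference point) is recorded per
#' generation and is non-decreasing.
#'
#' @param box a \code{\link{search_box}}-style data.frame (\code{name},
#'   \code{lower}, \code{upper}, \code{start}); any subset of rows.
#' @param obs observation set for f1 (ignored when \code{objective_fn} is
#'   given).
#' @param fixed full parameter vector supplying everything outside the box.
#' @param population,generations search budget.
#' @param seed integer seed controlling all optimizer randomness.
#' @param seed_points optional matrix/data.frame of parameter vectors
#'   (columns named as \code{box$name}) injected into the initial
#'   population, e.g. the published best fit.
#' @param objective_fn optional replacement objective,
#'   \code{function(x) c(f1, f2)} with \code{x} named as \code{box$name};
#'   defaults to \code{\link{evaluate_objectives}} on the simulator.
#' @param eval_duration passed to \code{\link{evaluate_objectives}}.
#' @param verbose print per-generation progress.
#' @return object of class \code{caulo_fit}: \code{archive} (nondominated
#'   data.frame of parameters + f1 + f2), \code{history} (per-generation
#'   hypervolume), \code{box}, \code{seed}, \code{n_eval}.
#' @export
optimize_mop <- function(box = search_box(), obs = NULL,
                         fixed = caulo_params(),
                         population = 40, generations = 25, seed = 1,
                         seed_points = NULL, objective_fn = NULL,
                         eval_duration = 900, verbose = FALSE) {
  stopifnot(population >= 4, generations >= 1)
  if (any(box$lower >= box$upper)) stop("infeasible box: lower >= upper")
  lower <- box$lower; upper <- box$upper
  p <- nrow(box)
  if (is.null(objective_fn)) {
    if (is.null(obs)) stop("obs is required unless objective_fn is given")
    objective_fn <- function(x)
      evaluate_objectives(stats::setNames(x, box$name), obs, fixed,
                          eval_duration = eval_duration)
  }
  set.seed(seed)
  pop <- matrix(stats::runif(population * p, rep(lower, each = population),
                             rep(upper, each = population)),
                nrow = population)
  pop[1, ] <- box$start
  if (!is.null(seed_points)) {
    sp <- as.matrix(as.data.frame(seed_points)[, box$name, drop = FALSE])
    k <- min(nrow(sp), population - 1)
    pop[1 + seq_len(k), ] <- sp[seq_len(k), , drop = FALSE]
  }
  colnames(pop) <- box$name
  eval_pop <- function(P) t(apply(P, 1, function(x) {
    f <- objective_fn(stats::setNames(x, box$name))
    c(f1 = unname(f[1]), f2 = unname(f[2]))
  }))
  F <- eval_pop(pop)
  n_eval <- population
  archive <- nondominated_filter(data.frame(pop, F, check.names = FALSE))
  ref <- c(max(F[, 1]), max(F[, 2])) * 1.1 + 1e-9
  history <- hypervolume2d(archive, ref)

  for (g in seq_len(generations)) {
    rank <- nds_rank(F)
    crowd <- numeric(population)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- crowding_distance(F[idx, , drop = FALSE])
    }
    tournament <- function() {
      ij <- sample.int(population, 2)
      i <- ij[1]; j <- ij[2]
      if (rank[i] < rank[j]) i
      else if (rank[j] < rank[i]) j
      else if (crowd[i] >= crowd[j]) i else j
    }
    children <- matrix(NA_real_, population, p)
    k <- 1
    while (k <= population) {
      pair <- sbx_crossover(pop[tournament(), ], pop[tournament(), ],
                            lower, upper)
      children[k, ] <- poly_mutate(pair[1, ], lower, upper)
      if (k + 1 <= population)
        children[k + 1, ] <- poly_mutate(pair[2, ], lower, upper)
      k <- k + 2
    }
    colnames(children) <- box$name
    Fc <- eval_pop(children)
    n_eval <- n_eval + population
    allP <- rbind(pop, children)
    allF <- rbind(F, Fc)
    r_all <- nds_rank(allF)
    cr_all <- numeric(nrow(allF))
    for (r in unique(r_all)) {
      idx <- which(r_all == r)
      cr_all[idx] <- crowding_distance(allF[idx, , drop = FALSE])
    }
    keep <- order(r_all, -cr_all)[seq_len(population)]
    pop <- allP[keep, , drop = FALSE]
    F <- allF[keep, , drop = FALSE]
    archive <- nondominated_filter(
      rbind(archive, data.frame(children, Fc, check.names = FALSE)))
    history <- c(history, hypervolume2d(archive, ref))
    if (verbose)
      message(sprintf("gen %3d  archive %3d  hv %.6g", g, nrow(archive),
                      history[length(history)]))
  }
  structure(list(archive = archive, history = history, box = box,
                 seed = seed, n_eval = n_eval, ref = ref),
            class = "caulo_fit")
}

#' @export
print.caulo_fit <- function(x, ...) {
  cat("<caulo_fit> NSGA-II archive: ", nrow(x$archive), " nondominated points, ",
      x$n_eval, " evaluations\n", sep = "")
  cat("  best f1: ", format(min(x$archive$f1), digits = 6),
      "   best f2: ", format(min(x$archive$f2), digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
plot.caulo_fit <- function(x, ...) {
  graphics::plot(x$archive$f1, x$archive$f2, xlab = "f1 (trajectory misfit)",
                 ylab = "f2 (|Tc - 150| min)", pch = 19, ...)
  invisible(x)
}

#' Parameter perturbation sensitivity of the two objectives
#'
#' Perturbs parameter vectors by a fixed relative magnitude and reports the
#' mean relative change of each objective.  Points whose baseline f2 is
#' near zero are excluded from the f2 average (the relative change there is
#' unboundedly large by construction).
#'
#' @param chi_points data.frame/matrix of parameter vectors (rows), columns
#'   named as in the search box.
#' @param magnitude relative perturbation, e.g. 0.1 for 10\%.
#' @param obs,fixed,eval_duration objective context (as in
#'   \code{\link{evaluate_objectives}}); ignored when \code{objective_fn}
#'   is given.
#' @param n_draws perturbation draws per point.
#' @param seed RNG seed.
#' @param mode \code{"uniform"}: one random sign per draw scales the whole
#'   vector by \code{1 +/- magnitude} (any degree-1 homogeneous objective
#'   then changes by exactly \code{magnitude}); \code{"independent"}:
#'   per-parameter random signs.
#' @param objective_fn optional \code{function(x) c(f1, f2)} override.
#' @param f2_exclude_below baseline-f2 threshold under which a point is
#'   dropped from the f2 sensitivity average.
#' @return list with \code{f1}, \code{f2} (mean |df/f|), \code{n_points_f2}
#'   (points retained for f2), \code{baselines}.
#' @export
perturbation_sensitivity <- function(chi_points, magnitude = 0.1,
                                     obs = NULL, fixed = caulo_params(),
                                     n_draws = 10, seed = 1,
                                     mode = c("uniform", "independent"),
                                     objective_fn = NULL,
                                     eval_duration = 900,
                                     f2_exclude_below = 0.5) {
  mode <- match.arg(mode)
  if (magnitude < 0 || magnitude >= 1) stop("magnitude must be in [0, 1)")
  chi <- as.matrix(as.data.frame(chi_points))
  if (is.null(objective_fn)) {
    if (is.null(obs)) stop("obs is required unless objective_fn is given")
    objective_fn <- function(x)
      evaluate_objectives(x, obs, fixed, eval_duration = eval_duration)
  }
  set.seed(seed)
  base <- t(apply(chi, 1, function(x)
    objective_fn(stats::setNames(x, colnames(chi)))))
  rel1 <- rel2 <- numeric()
  use2 <- abs(base[, 2]) >= f2_exclude_below
  for (i in seq_len(nrow(chi))) {
    for (d in seq_len(n_draws)) {
      fac <- if (mode == "uniform")
        1 + magnitude * sample(c(-1, 1), 1)
      else 1 + magnitude * sample(c(-1, 1), ncol(chi), replace = TRUE)
      f <- objective_fn(stats::setNames(chi[i, ] * fac, colnames(chi)))
      if (base[i, 1] > 0) rel1 <- c(rel1, abs(f[1] - base[i, 1]) / base[i, 1])
      if (use2[i]) rel2 <- c(rel2, abs(f[2] - base[i, 2]) / base[i, 2])
    }
  }
  if (!any(use2) && !length(rel1))
    stop("all baselines degenerate; sensitivity undefined")
  list(f1 = if (length(rel1)) mean(rel1) else NA_real_,
       f2 = if (length(rel2)) mean(rel2) else NA_real_,
       n_points_f2 = sum(use2), baselines = base)
}

#' Refit a subset of parameters to an observation set
#'
#' Local derivative-free minimization of the trajectory misfit f1 over a
#' handful of parameters (all others fixed), used for parameter-recovery
#' checks: Nelder-Mead on a logit-box transform so iterates respect the
#' bounds.
#'
#' @param start named numeric starting values (the perturbed parameters).
#' @param obs observation set (typically a noiseless synthetic fixture).
#' @param fixed full parameter vector for everything else.
#' @param box bounds data.frame (rows matching \code{names(start)} are
#'   used).
#' @param eval_duration objective simulation length (min).
#' @param maxit Nelder-Mead iteration budget per stage.
#' @param restarts simplex restarts from the incumbent (Nelder-Mead
#'   collapses on curved ridges; re-inflating the simplex resumes descent).
#' @return list with \code{par} (refitted values), \code{f1}, and
#'   \code{convergence}.
#' @export
refit_parameters <- function(start, obs, fixed = caulo_params(),
                             box = search_box(), eval_duration = 450,
                             maxit = 150, restarts = 2) {
  nm <- names(start)
  b <- box[match(nm, box$name), ]
  if (anyNA(b$name)) stop("parameters not in box: ",
                          paste(nm[is.na(b$name)], collapse = ", "))
  to_unit <- function(x) stats::qlogis(pmin(pmax((x - b$lower) /
                                                   (b$upper - b$lower),
                                                 1e-6), 1 - 1e-6))
  from_unit <- function(u) b$lower + stats::plogis(u) * (b$upper - b$lower)
  fn <- function(u) {
    x <- stats::setNames(from_unit(u), nm)
    evaluate_objectives(x, obs, fixed, eval_duration = eval_duration)[["f1"]]
  }
  u <- to_unit(unname(start))
  opt <- stats::optim(u, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  for (r in seq_len(restarts)) {
    if (opt$value < 1e-12) break
    opt2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
  }
  list(par = stats::setNames(from_unit(opt$par), nm), f1 = opt$value,
       convergence = opt$convergence)
}
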