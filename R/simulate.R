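#' Simulate the hybrid cell-cycle model
#'
#' Integrates the 29-state ODE system with stiff-capable adaptive stepping
#' (\code{deSolve::lsodar}) and exact event location for the five discrete
#' replication/division milestones.  Integration restarts with fresh solver
#' state after every event, respecting the discontinuity.
#'
#' @param params parameter vector from \code{\link{caulo_params}}.
#' @param init initial state from \code{\link{caulo_state}}.
#' @param duration simulated time, minutes.
#' @param qssa logical; replace Complex 3 by its quasi-steady state
#'   (\eqn{k_3^+ [cdG]^2 [Complex2] / k_3^-}).
#' @param out_step dense-output spacing in minutes (event times are always
#'   included exactly).
#' @param rtol,atol relative/absolute integration tolerances.
#' @param hmax maximum solver step (min); kept small enough that no
#'   threshold crossing can be skipped.
#' @param plec_mode \code{"cycle"} (default) re-zeroes the PleC forcing
#'   clock at each division (Z-ring event) so that every cycle experiences
#'   the same phosphatase profile, which is how the single-cycle forcing fit
#'   is defined; \code{"absolute"} evaluates it on absolute simulation time.
#' @param elong_at_initiation \code{Elong} seed applied by the initiation
#'   event (0.1 bidirectional-fork convention, the default; 0.05 for the
#'   single-fork convention).
#' @param engine \code{"compiled"} (C right-hand side and root function,
#'   the default) or \code{"r"} (reference R implementation); both give
#'   identical trajectories to solver precision.
#' @return object of class \code{caulo_sim}: list with \code{time},
#'   \code{state} (matrix, one column per state plus \code{DNA},
#'   \code{Count}, \code{ks_Zring}), \code{events} (data.frame: event, time,
#'   cycle), \code{params}, and solver metadata.
#' @examples
#' \donttest{
#' sim <- simulate_caulobacter(duration = 600)
#' summary(sim)
#' }
#' @export
simulate_caulobacter <- function(params = caulo_params(),
                                 init = caulo_state(),
                                 duration = 600,
                                 qssa = FALSE,
                                 out_step = 1,
                                 rtol = 1e-8, atol = 1e-10, hmax = 1,
                                 plec_mode = c("cycle", "absolute"),
                                 elong_at_initiation = 0.1,
                                 engine = c("compiled", "r")) {
  plec_mode <- match.arg(plec_mode)
  engine <- match.arg(engine)
  stopifnot(duration >= 0)
  validate_params(params)
  rules <- builtin_event_table(params, elong_at_initiation)
  y <- stats::setNames(as.numeric(init), names(init))
  mode <- list(DNA = attr(init, "DNA") %||% 1,
               Count = attr(init, "Count") %||% 1,
               ks_Zring = attr(init, "ks_Zring") %||% 0)
  empty_log <- data.frame(event = character(), time = numeric(),
                          cycle = integer(), stringsAsFactors = FALSE)
  if (duration == 0) {
    st <- matrix(c(y, mode$DNA, mode$Count, mode$ks_Zring), nrow = 1,
                 dimnames = list(NULL, c(names(y), "DNA", "Count", "ks_Zring")))
    return(new_caulo_sim(0, st, empty_log, params, qssa, rtol, atol,
                         out_step, plec_mode, elong_at_initiation))
  }

  # event arming: fork/termination roots are live only during replication,
  # the initiation root only outside it (once per round), the Z-ring root
  # only while its clock runs
  replicating <- y[["Elong"]] > 0 && y[["Elong"]] < params[["Elong_term"]]
  armed <- c(initiation = !replicating,
             fork_ccrM = replicating && y[["Elong"]] < params[["Elong_ccrM"]],
             fork_ctrA = replicating && y[["Elong"]] < params[["Elong_ctrA"]],
             termination = replicating,
             zring = mode$ks_Zring > 0)
  plec_t0 <- if (plec_mode == "cycle") 0 else 0  # updated at divisions
  cycle <- 0L
  t_cur <- 0
  grid <- seq(0, duration, by = out_step)
  if (grid[length(grid)] < duration) grid <- c(grid, duration)

  rows <- vector("list", 64L); nrows <- 0L
  log <- empty_log
  add_rows <- function(m) {
    nrows <<- nrows + 1L
    rows[[nrows]] <<- m
  }

  if (engine == "r") {
    rhs <- make_rhs(params, qssa)
    deriv <- function(t, y, parms) rhs(t, y, mode$ks_Zring, plec_t0)
    rootfun <- function(t, y, parms) {
      vapply(seq_along(rules), function(i) {
        r <- rules[[i]]
        if (armed[[r$id]]) unname(y[[r$trigger]] - r$threshold) else 1
      }, numeric(1))
    }
  }

  repeat {
    times <- c(t_cur, grid[grid > t_cur + 1e-12])
    if (length(times) < 2) break
    out <- if (engine == "compiled") {
      seg <- deSolve::lsodar(y = y, times = times, func = "caulo_derivs",
                             parms = rhs_parm_vector(params, mode$ks_Zring,
                                                     plec_t0, qssa, armed),
                             dllname = "caulocycle",
                             initfunc = "caulo_initmod",
                             rootfunc = "caulo_root", nroot = 5L,
                             rtol = rtol, atol = atol,
                             hmax = hmax, maxsteps = 1e5)
      colnames(seg) <- c("time", names(y))
      seg
    } else {
      deSolve::lsodar(y = y, times = times, func = deriv, parms = params,
                      rootfunc = rootfun, rtol = rtol, atol = atol,
                      hmax = hmax, maxsteps = 1e5)
    }
    if (attr(out, "istate")[1] < 0)
      stop("integration failure at t = ", out[nrow(out), 1],
           " (istate = ", attr(out, "istate")[1], ")")
    seg <- out[, , drop = FALSE]
    if (t_cur > 0) seg <- seg[-1, , drop = FALSE]   # drop duplicated start
    if (nrow(seg)) {
      sm <- seg[, -1, drop = FALSE]
      sm[sm < 0 & sm > -1e-8] <- 0
      add_rows(cbind(time = seg[, 1], sm,
                     DNA = mode$DNA, Count = mode$Count,
                     ks_Zring = mode$ks_Zring))
    }
    t_last <- out[nrow(out), 1]
    y <- out[nrow(out), -1]
    iroot <- attr(out, "iroot")
    if (is.null(iroot) || !any(iroot != 0) || t_last >= duration - 1e-10) {
      t_cur <- t_last
      if (t_cur >= duration - 1e-10) break else next
    }
    # apply triggered rule(s) in table order
    fire_rule <- function(r) {
      res <- apply_event(r, y, mode)
      y <<- res$y; mode <<- res$mode
      if (r$id == "initiation") {
        cycle <<- cycle + 1L
        armed["initiation"] <<- FALSE
        armed["fork_ccrM"] <<- TRUE
        armed["fork_ctrA"] <<- TRUE
        armed["termination"] <<- TRUE
        armed["zring"] <<- TRUE
      } else if (r$id == "fork_ccrM") {
        armed["fork_ccrM"] <<- FALSE
      } else if (r$id == "fork_ctrA") {
        armed["fork_ctrA"] <<- FALSE
      } else if (r$id == "termination") {
        armed["termination"] <<- FALSE
        armed["fork_ccrM"] <<- FALSE
        armed["fork_ctrA"] <<- FALSE
        armed["initiation"] <<- TRUE
      } else if (r$id == "zring") {
        armed["zring"] <<- FALSE
        if (plec_mode == "cycle") plec_t0 <<- t_last
      }
      log <<- rbind(log, data.frame(event = r$id, time = t_last,
                                    cycle = max(cycle, 1L),
                                    stringsAsFactors = FALSE))
      # post-event sample so the dense record shows the discontinuity
      add_rows(matrix(c(t_last, y, mode$DNA, mode$Count, mode$ks_Zring),
                      nrow = 1,
                      dimnames = list(NULL, c("time", names(y), "DNA",
                                              "Count", "ks_Zring"))))
    }
    for (i in which(iroot != 0)) fire_rule(rules[[i]])
    # a replication round that outlasts the next initiation signal: the
    # one-shot guard holds initiation until termination, then fires it
    if (armed[["initiation"]] && y[["Ini"]] >= params[["P_elong"]])
      fire_rule(rules[[1]])
    t_cur <- t_last
  }

  tab <- do.call(rbind, rows[seq_len(nrows)])
  st <- tab[, -1, drop = FALSE]
  if (qssa) {
    p <- params
    st[, "Complex3"] <- p[["k3_plus"]] * st[, "cdG"]^2 *
      st[, "Complex2"] / p[["k3_minus"]]
  }
  new_caulo_sim(tab[, 1], st, log, params, qssa, rtol, atol,
                out_step, plec_mode, elong_at_initiation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_caulo_sim <- function(time, state, events, params, qssa, rtol, atol,
                          out_step, plec_mode, elong_at_initiation) {
  structure(list(time = as.numeric(time), state = state, events = events,
                 params = params, qssa = qssa,
                 solver = list(rtol = rtol, atol = atol, out_step = out_step,
                               plec_mode = plec_mode,
                               elong_at_initiation = elong_at_initiation),
                 params_hash = param_hash(params)),
            class = "caulo_sim")
}

# cheap provenance fingerprint (no digest dependency)
param_hash <- function(p) {
  v <- format(as.numeric(p), digits = 15)
  sum(cumsum(utf8ToInt(paste(names(p), v, collapse = "|"))) %% 2147483647)
}

#' QSSA variant of \code{\link{simulate_caulobacter}}
#'
#' Convenience wrapper running the model with Complex 3 at its algebraic
#' quasi-steady state.
#' @inheritParams simulate_caulobacter
#' @param ... passed on to \code{\link{simulate_caulobacter}}.
#' @export
simulate_qssa <- function(params = caulo_params(), init = caulo_state(),
                          duration = 600, ...) {
  simulate_caulobacter(params, init, duration, qssa = TRUE, ...)
}

#' @export
print.caulo_sim <- function(x, ...) {
  cat("<caulo_sim> ", if (x$qssa) "(QSSA) " else "",
      format(max(x$time), digits = 6), " min, ",
      length(x$time), " samples, ", nrow(x$events), " events\n", sep = "")
  if (nrow(x$events)) {
    ini <- x$events$time[x$events$event == "initiation"]
    cat("  initiations at:", paste(format(ini, digits = 5), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
summary.caulo_sim <- function(object, ...) {
  m <- cycle_metrics(object)
  print(m)
  invisible(m)
}

#' Coerce a simulation to a data frame
#' @param x a \code{caulo_sim}.
#' @param row.names,optional ignored (base generic signature).
#' @param format \code{"wide"} (one column per state) or \code{"long"}
#'   (time, variable, value).
#' @param ... ignored.
#' @export
as.data.frame.caulo_sim <- function(x, row.names = NULL, optional = FALSE,
                                    format = c("wide", "long"), ...) {
  format <- match.arg(format)
  wide <- data.frame(time = x$time, x$state, check.names = FALSE)
  if (format == "wide") return(wide)
  vars <- setdiff(colnames(wide), "time")
  data.frame(
    time = rep(wide$time, times = length(vars)),
    variable = rep(vars, each = nrow(wide)),
    value = unlist(wide[vars], use.names = FALSE)
  )
}

#' Plot state trajectories
#' @param x a \code{caulo_sim}.
#' @param vars state variables to draw (default: the five master regulators
#'   with total CtrA).
#' @param ... passed to \code{matplot}.
#' @export
plot.caulo_sim <- function(x, vars = c("DnaA", "GcrA", "CcrM", "SciP"), ...) {
  st <- species_series(x, c(vars, "CtrA"))
  graphics::matplot(x$time, st, type = "l", lty = 1,
                    xlab = "time (min)", ylab = "concentration (a.u.)", ...)
  graphics::legend("topright", legend = colnames(st), col = seq_len(ncol(st)),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Extract (possibly composite) species time series
#'
#' Observable species map onto model states as measured by immunoblots:
#' \code{CtrA}, \code{CpdR} and \code{PleD} are the totals over their
#' phosphoforms; all other names are read directly.
#'
#' @param sim a \code{caulo_sim}.
#' @param species character vector of observable names.
#' @return numeric matrix, one column per species.
#' @export
species_series <- function(sim, species) {
  st <- sim$state
  out <- sapply(species, function(sp) {
    switch(sp,
           CtrA = st[, "CtrA"] + st[, "CtrAP"],
           CpdR = st[, "CpdR"] + st[, "CpdRP"],
           PleD = st[, "PleD"] + st[, "PleDP"],
           {
             if (!sp %in% colnames(st)) stop("unknown species: ", sp)
             st[, sp]
           })
  })
  matrix(out, ncol = length(species), dimnames = list(NULL, species))
}
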