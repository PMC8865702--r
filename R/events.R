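#' Built-in discrete event rules of the cell cycle
#'
#' The five threshold events punctuating each replication round.  Every rule
#' fires on an upward crossing of its trigger variable and applies its
#' assignments instantaneously; all other state variables are continuous
#' across the event.
#'
#' \describe{
#'   \item{initiation}{\code{Ini} reaches \code{P_elong}: replication starts.
#'     Resets \code{Ini} to 0, seeds \code{Elong} (0.1 by default, the
#'     bidirectional-fork convention), flips \code{hCori} to 1 (origin
#'     freshly hemimethylated), starts the Z-ring clock
#'     (\code{ks_Zring = 0.011}), and sets the bookkeeping \code{DNA = 1.05},
#'     \code{Count = 2}.  One-shot: cannot re-fire until termination.}
#'   \item{fork_ccrM}{\code{Elong} reaches 0.2: fork passes the ccrM locus,
#'     \code{hccrM = 1}.}
#'   \item{fork_ctrA}{\code{Elong} reaches 0.375: fork passes the ctrA locus,
#'     \code{hctrA = 1}.}
#'   \item{termination}{\code{Elong} reaches 1: elongation done,
#'     \code{Elong = 0}.}
#'   \item{zring}{\code{Zring} reaches 1: Z-ring constriction separates the
#'     chromosomes; \code{Zring = 0}, clock off (\code{ks_Zring = 0}),
#'     \code{DNA = 1}, \code{Count = 1}.}
#' }
#'
#' @param p a \code{\link{caulo_params}} vector (supplies the thresholds).
#' @param elong_at_initiation \code{Elong} value planted at initiation:
#'   0.1 (= 2 P_elong, the default) counts both forks of bidirectional
#'   replication; 0.05 is the single-fork convention.
#' @return list of event rules (class \code{caulo_events}), in tie-break
#'   (application) order.
#' @export
builtin_event_table <- function(p = caulo_params(), elong_at_initiation = 0.1) {
  rules <- list(
    list(id = "initiation", trigger = "Ini",
         threshold = unname(p[["P_elong"]]), direction = "up",
         assignments = list(Ini = 0, Elong = elong_at_initiation, hCori = 1),
         mode = list(DNA = 1.05, Count = 2, ks_Zring = unname(p[["ks_Zring_on"]])),
         one_shot_per_cycle = TRUE),
    list(id = "fork_ccrM", trigger = "Elong",
         threshold = unname(p[["Elong_ccrM"]]), direction = "up",
         assignments = list(hccrM = 1), mode = list(),
         one_shot_per_cycle = TRUE),
    list(id = "fork_ctrA", trigger = "Elong",
         threshold = unname(p[["Elong_ctrA"]]), direction = "up",
         assignments = list(hctrA = 1), mode = list(),
         one_shot_per_cycle = TRUE),
    list(id = "termination", trigger = "Elong",
         threshold = unname(p[["Elong_term"]]), direction = "up",
         assignments = list(Elong = 0), mode = list(),
         one_shot_per_cycle = TRUE),
    list(id = "zring", trigger = "Zring",
         threshold = unname(p[["Zring_div"]]), direction = "up",
         assignments = list(Zring = 0), mode = list(DNA = 1, Count = 1, ks_Zring = 0),
         one_shot_per_cycle = TRUE)
  )
  structure(rules, class = "caulo_events")
}

#' Apply an event rule's assignments to a state
#'
#' @param rule one element of \code{\link{builtin_event_table}}.
#' @param y named continuous state vector.
#' @param mode named list with \code{DNA}, \code{Count}, \code{ks_Zring}.
#' @return list with updated \code{y} and \code{mode}.
#' @keywords internal
apply_event <- function(rule, y, mode) {
  for (nm in names(rule$assignments)) {
    if (!nm %in% names(y)) stop("event assigns unknown state: ", nm)
    y[[nm]] <- rule$assignments[[nm]]
  }
  for (nm in names(rule$mode)) mode[[nm]] <- rule$mode[[nm]]
  list(y = y, mode = mode)
}

#' Locate a threshold crossing and apply the event
#'
#' Root-finds the time at which \code{rule$trigger} crosses its threshold
#' (upward) inside a bracketing interval, then applies the rule's
#' assignments atomically.  \code{statefun(t)} must return the named
#' continuous state at time \code{t}; in practice this is a dense-output
#' interpolant or a re-integration from the left bracket.
#'
#' @param rule an event rule.
#' @param statefun function of time returning the named state vector.
#' @param t1,t2 bracketing times with the trigger below threshold at
#'   \code{t1} and at/above it at \code{t2}.
#' @param mode mode list as in \code{\link{apply_event}}.
#' @param tol time tolerance for the crossing (min).
#' @return list with \code{time}, post-event \code{y} and \code{mode}.
#' @export
locate_and_apply <- function(rule, statefun, t1, t2,
                             mode = list(DNA = 1, Count = 1, ks_Zring = 0),
                             tol = 1e-8) {
  g <- function(t) statefun(t)[[rule$trigger]] - rule$threshold
  g1 <- g(t1); g2 <- g(t2)
  if (g1 > 0 || g2 < 0)
    stop("locate_and_apply: trigger does not cross threshold upward in [t1, t2]")
  t_ev <- if (g2 == 0) t2 else
    stats::uniroot(g, c(t1, t2), tol = tol)$root
  post <- apply_event(rule, statefun(t_ev), mode)
  c(list(time = t_ev), post)
}
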