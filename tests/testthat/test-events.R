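test_that("the built-in event table encodes the five replication milestones", {
  p <- caulo_params()
  ev <- builtin_event_table(p)
  expect_length(ev, 5)
  ids <- vapply(ev, `[[`, "", "id")
  expect_identical(ids, c("initiation", "fork_ccrM", "fork_ctrA",
                          "termination", "zring"))
  thr <- vapply(ev, `[[`, 0, "threshold")
  expect_equal(thr, c(0.05, 0.2, 0.375, 1, 1))
  ini <- ev[[1]]
  expect_equal(ini$assignments$Ini, 0)
  expect_equal(ini$assignments$hCori, 1)
  expect_equal(ini$assignments$Elong, 0.1)
  expect_equal(ini$mode$ks_Zring, 0.011)
  expect_equal(ini$mode$DNA, 1.05)
  expect_equal(ini$mode$Count, 2)
  expect_equal(builtin_event_table(p, 0.05)[[1]]$assignments$Elong, 0.05)
  zr <- ev[[5]]
  expect_equal(zr$assignments$Zring, 0)
  expect_equal(zr$mode$ks_Zring, 0)
  expect_equal(zr$mode$DNA, 1)
  expect_equal(zr$mode$Count, 1)
  expect_true(all(vapply(ev, function(r) r$direction == "up", TRUE)))
})

test_that("locate_and_apply root-finds the crossing and applies assignments", {
  rules <- builtin_event_table()
  term <- rules[[4]]
  # synthetic linear elongation: crosses Elong = 1 at exactly t = 5
  statefun <- function(t) {
    y <- setNames(as.numeric(caulo_state()), caulo_state_names())
    y["Elong"] <- 0.5 + 0.1 * t
    y["CtrA"] <- 2 + 0.3 * t
    y
  }
  res <- locate_and_apply(term, statefun, 0, 8)
  expect_equal(res$time, 5, tolerance = 1e-8)
  expect_equal(res$y[["Elong"]], 0)             # reset applied
  expect_equal(res$y[["CtrA"]], 2 + 0.3 * res$time, tolerance = 1e-6)
  # no crossing in the bracket
  expect_error(locate_and_apply(term, statefun, 0, 2), "does not cross")
  # z-ring rule flips mode flags atomically
  zfun <- function(t) {
    y <- statefun(t); y["Zring"] <- 0.2 * t; y
  }
  rz <- locate_and_apply(rules[[5]], zfun, 0, 8,
                         mode = list(DNA = 1.05, Count = 2, ks_Zring = 0.011))
  expect_equal(rz$time, 5, tolerance = 1e-8)
  expect_equal(rz$mode$ks_Zring, 0)
  expect_equal(rz$mode$Count, 1)
})

test_that("wild-type cycles fire events in the realized order, once per cycle", {
  sim <- wt_sim()
  log <- sim$events
  ini <- log$time[log$event == "initiation"]
  expect_gte(length(ini), 3)
  # within each replication round the milestones are strictly ordered:
  # initiation, fork passage at ccrM (Elong 0.2) then ctrA (0.375), Z-ring
  # constriction ~91 min later; termination of the slow elongation variable
  # closes the round before the next initiation
  for (k in seq_len(length(ini) - 1)) {
    inwin <- log[log$time >= ini[k] & log$time < ini[k + 1], ]
    expect_equal(sum(inwin$event == "initiation"), 1)
    expect_equal(sum(inwin$event == "fork_ccrM"), 1)
    expect_equal(sum(inwin$event == "fork_ctrA"), 1)
    tc <- inwin$time[inwin$event == "fork_ccrM"]
    ta <- inwin$time[inwin$event == "fork_ctrA"]
    tz <- inwin$time[inwin$event == "zring"]
    expect_true(tc < ta)
    expect_true(ta < tz)
  }
  # exactly one termination separates consecutive initiations
  term <- log$time[log$event == "termination"]
  for (k in seq_len(length(ini) - 1))
    expect_equal(sum(term > ini[k] & term <= ini[k + 1]), 1)
})

test_that("event times are robust to integrator tolerance changes", {
  s1 <- simulate_caulobacter(duration = 500)
  s2 <- simulate_caulobacter(duration = 500, rtol = 5e-9, atol = 5e-11)
  expect_identical(s1$events$event, s2$events$event)
  expect_lt(max(abs(s1$events$time - s2$events$time)), 0.01)
})
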