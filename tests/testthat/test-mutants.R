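test_that("mutant overrides are the only difference from wild type", {
  wt <- caulo_params()
  for (spec in builtin_panel()) {
    mut <- apply_mutant(wt, spec)
    changed <- names(wt)[as.numeric(mut) != as.numeric(wt)]
    expect_setequal(changed, names(spec$overrides))
    for (nm in names(spec$overrides))
      expect_equal(unname(mut[[nm]]), spec$overrides[[nm]])
  }
  # lookup by name, and the documented error paths
  expect_equal(unname(apply_mutant(wt, "dccrM")[["ks_ccrM"]]), 0)
  expect_error(apply_mutant(wt, "dXyz"), "built-in panel")
  expect_error(apply_mutant(wt, list(bogus = 1)), "unknown parameter")
})

test_that("the built-in panel covers the published strain collection", {
  panel <- builtin_panel()
  expect_length(panel, 11)
  expect_identical(panel$ddnaA$expected, "arrested")
  expect_equal(panel$dccrM$overrides$ks_ccrM, 0)
  expect_equal(panel$ctrAD3O$overrides$kd_CtrA_ClpXP, 0.1 * 0.053)
  expect_equal(panel$cdG0$overrides$ks_cdG, 0)
  expect_match(panel$dpleD$note, "lower mean cdG")
  expect_setequal(names(panel$JdAll0$overrides),
                  c("Jd_CtrA_ClpXP", "Jd_CpdR", "Jd_RcdA"))
  osc <- vapply(panel, `[[`, "", "expected")
  expect_equal(sum(osc == "oscillatory"), 6)
  expect_equal(sum(osc == "defective"), 4)
})

test_that("ccrM knockout lengthens the cycle and locks hemimethylation", {
  sim <- cached_sim("dccrM1500",
                    simulate_caulobacter(caulo_params(ks_ccrM = 0),
                                         duration = 1500, out_step = 2))
  m <- classify_phenotype(sim)
  expect_identical(m$phenotype, "oscillatory")
  expect_gt(m$period, cycle_period(wt_sim())$period + 5)
  # with no methyltransferase, no locus ever returns to full methylation
  first_fork <- min(sim$events$time[sim$events$event == "fork_ccrM"])
  after <- sim$time > first_fork + 1
  expect_true(all(sim$state[after, "hccrM"] > 0))
  first_ini <- min(sim$events$time[sim$events$event == "initiation"])
  expect_true(all(sim$state[sim$time > first_ini + 1, "hCori"] > 0))
})

test_that("classify_phenotype distinguishes oscillatory from arrested", {
  m_wt <- classify_phenotype(wt_sim())
  expect_identical(m_wt$phenotype, "oscillatory")
  expect_lt(abs(m_wt$period - 150), 2)
  arr <- simulate_caulobacter(caulo_params(ks_dnaA = 0), duration = 700)
  expect_identical(classify_phenotype(arr)$phenotype, "arrested")
})

test_that("scenario driver writes a complete artifact manifest", {
  out <- file.path(tempdir(), "caulo_run")
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  man <- run_scenario(list(scenario = "wildtype", duration = 500,
                           out_dir = out, seed = 1), verbose = FALSE)
  expect_true(all(file.exists(man$path)))
  expect_true(any(grepl("trajectory", man$artifact)))
  expect_true(any(grepl("events", man$artifact)))
  expect_true(any(grepl("metrics", man$artifact)))
  met <- utils::read.table(file.path(out, "wildtype_metrics.tsv"),
                           header = TRUE)
  expect_true(met$period > 100)
  # byte-identical reproduction under the same config and seed
  out2 <- file.path(tempdir(), "caulo_run2")
  on.exit(unlink(out2, recursive = TRUE), add = TRUE)
  run_scenario(list(scenario = "wildtype", duration = 500,
                    out_dir = out2, seed = 1), verbose = FALSE)
  f1 <- file.path(out, "wildtype_metrics.tsv")
  f2 <- file.path(out2, "wildtype_metrics.tsv")
  expect_identical(readLines(f1), readLines(f2))
  expect_error(run_scenario(list(scenario = "dNope", out_dir = out),
                            verbose = FALSE), "valid")
  expect_error(run_scenario(list(out_dir = out, duration = -5),
                            verbose = FALSE), "duration")
  # qssa comparison scenario emits paired outputs and difference metrics
  out3 <- file.path(tempdir(), "caulo_run3")
  on.exit(unlink(out3, recursive = TRUE), add = TRUE)
  man3 <- run_scenario(list(scenario = "qssa-compare", duration = 500,
                            out_dir = out3), verbose = FALSE)
  expect_true(any(grepl("qssa_metrics", man3$artifact)))
  cmp <- utils::read.table(file.path(out3, "qssa_comparison.tsv"),
                           header = TRUE)
  expect_true(is.finite(cmp$ctrA_rms_over_amp))
})
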