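test_that("the search box matches the published 47-parameter design", {
  box <- search_box()
  expect_equal(nrow(box), 47)
  expect_true(all(box$lower < box$upper))
  expect_true(all(box$start >= box$lower & box$start <= box$upper))
  expect_true(all(box$name %in% names(caulo_params())))
  expect_true(all(!duplicated(box$name)))
})

test_that("f1 implements the mean-squared misfit as printed", {
  sim <- wt_eval_sim()
  # one species, two points: residuals (0, 1) -> f1 = 0.5
  obs <- generate_observations(sim, species = "CtrA", n_points = 2,
                               noise_sd = 0, seed = 9)
  obs1 <- obs
  obs1$value <- obs$value + c(0, 1)
  expect_equal(objective_f1(NULL, obs1), 0.5, tolerance = 1e-8)
  # adding a second species with zero error halves the per-species mean
  obs2 <- generate_observations(sim, species = c("CtrA", "DnaA"),
                                n_points = 2, noise_sd = 0, seed = 9)
  obs2$value[obs2$species == "CtrA"] <-
    obs2$value[obs2$species == "CtrA"] + c(0, 1)
  expect_equal(objective_f1(NULL, obs2), 0.25, tolerance = 1e-8)
  # pooled weighting divides by the total number of points instead
  expect_equal(objective_f1(NULL, obs2, weighting = "pooled"), 0.25,
               tolerance = 1e-8)
  # noiseless self-fixture is interpolated exactly
  full <- generate_observations(sim, n_points = 8, noise_sd = 0, seed = 2)
  expect_equal(objective_f1(NULL, full), 0)
})

test_that("f2 is the absolute cycle-period deviation from 150 min", {
  expect_lt(objective_f2(NULL), 0.5)                        # wild type
  f2_ccrM <- objective_f2(c(ks_ccrM = 0))
  expect_gt(f2_ccrM, 10); expect_lt(f2_ccrM, 17)            # ~|164 - 150|
  # arrested system gets the sentinel
  expect_equal(objective_f2(c(ks_dnaA = 0)), 1e6)
})

test_that("nondominated filtering matches a brute-force dominance check", {
  pts <- data.frame(f1 = c(1, 2, 2), f2 = c(2, 1, 2))
  nd <- nondominated_filter(pts)
  expect_equal(nrow(nd), 2)
  expect_setequal(nd$f1 + 10 * nd$f2, c(21, 12))
  expect_equal(nrow(nondominated_filter(pts[1, ])), 1)
  same <- data.frame(f1 = rep(3, 4), f2 = rep(7, 4))
  expect_equal(nrow(nondominated_filter(same)), 4)
  # random clouds against an independent double-loop oracle
  set.seed(7)
  for (rep in 1:5) {
    cloud <- data.frame(f1 = stats::runif(40), f2 = stats::runif(40))
    keep_oracle <- rep(TRUE, 40)
    for (i in 1:40) for (j in 1:40) {
      if (i != j &&
          cloud$f1[j] <= cloud$f1[i] && cloud$f2[j] <= cloud$f2[i] &&
          (cloud$f1[j] < cloud$f1[i] || cloud$f2[j] < cloud$f2[i]))
        keep_oracle[i] <- FALSE
    }
    nd <- nondominated_filter(cloud)
    expect_setequal(paste(nd$f1, nd$f2),
                    paste(cloud$f1[keep_oracle], cloud$f2[keep_oracle]))
  }
})

test_that("the evolutionary search solves a toy biobjective to the known front", {
  box <- data.frame(name = "kd_ctrA", lower = 0, upper = 2, start = 1)
  toy <- function(x) c(f1 = unname(x[1])^2, f2 = (unname(x[1]) - 2)^2)
  fit <- optimize_mop(box, objective_fn = toy, population = 40,
                      generations = 30, seed = 3)
  expect_s3_class(fit, "caulo_fit")
  # archive is feasible and internally nondominated
  expect_true(all(fit$archive$kd_ctrA >= 0 & fit$archive$kd_ctrA <= 2))
  expect_equal(nrow(nondominated_filter(fit$archive)), nrow(fit$archive))
  # hypervolume is monotone over generations and near the closed form
  expect_true(all(diff(fit$history) >= 0))
  ref <- c(4.5, 4.5)
  xs <- seq(0, 2, length.out = 4001)
  hv_true <- hypervolume2d(data.frame(f1 = xs^2, f2 = (xs - 2)^2), ref)
  expect_gt(hypervolume2d(fit$archive, ref), 0.95 * hv_true)
  # identical seed, identical archive
  fit2 <- optimize_mop(box, objective_fn = toy, population = 40,
                       generations = 30, seed = 3)
  expect_identical(fit$archive, fit2$archive)
  expect_error(optimize_mop(data.frame(name = "a", lower = 2, upper = 1,
                                       start = 1.5), objective_fn = toy),
               "infeasible")
})

test_that("seeding the population with the published fit keeps it on the front", {
  sim <- wt_eval_sim()
  obs <- generate_observations(sim, n_points = 6, noise_sd = 0, seed = 4)
  box <- search_box()
  seedpt <- as.data.frame(as.list(caulo_params()[box$name]))
  fit <- optimize_mop(box, obs = obs, population = 8, generations = 2,
                      seed = 11, seed_points = seedpt)
  expect_lte(min(fit$archive$f2), 0.1)
  expect_lte(min(fit$archive$f1), 1e-8)
})

test_that("perturbation sensitivity obeys its closed forms", {
  chi <- data.frame(a = c(1, 2), b = c(3, 1), cc = c(2, 2))
  lin <- function(x) c(f1 = sum(x), f2 = sum(x))
  # zero magnitude, zero change
  s0 <- perturbation_sensitivity(chi, 0, objective_fn = lin, n_draws = 3,
                                 f2_exclude_below = 0)
  expect_equal(s0$f1, 0)
  # degree-1 homogeneous objective: uniform +-10% changes it by exactly 10%
  s1 <- perturbation_sensitivity(chi, 0.1, objective_fn = lin, n_draws = 8,
                                 mode = "uniform", f2_exclude_below = 0)
  expect_equal(s1$f1, 0.1, tolerance = 1e-12)
  expect_equal(s1$f2, 0.1, tolerance = 1e-12)
  # near-zero f2 baselines are excluded from the f2 average
  near0 <- function(x) c(f1 = sum(x), f2 = 1e-9)
  s2 <- perturbation_sensitivity(chi, 0.1, objective_fn = near0, n_draws = 2)
  expect_equal(s2$n_points_f2, 0)
  expect_true(is.na(s2$f2))
  expect_error(perturbation_sensitivity(chi, 1.2, objective_fn = lin),
               "magnitude")
})
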