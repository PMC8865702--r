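test_that("Hill activation and inhibition match their closed forms", {
  expect_equal(hill_activation(0, 5, 2), 0)
  expect_equal(hill_activation(10, 5, 2), 0.8)     # 100 / 125
  expect_equal(hill_inhibition(0, 5, 2), 1)
  expect_equal(hill_inhibition(10, 5, 2), 0.2)
  # half-saturation identity for several exponents
  for (n in c(1, 2, 4)) {
    expect_equal(hill_activation(3.7, 3.7, n), 0.5)
    expect_equal(hill_inhibition(3.7, 3.7, n), 0.5)
  }
  # complement and monotonicity
  x <- seq(0, 20, by = 0.5)
  expect_equal(hill_activation(x, 4, 2) + hill_inhibition(x, 4, 2),
               rep(1, length(x)))
  expect_true(all(diff(hill_activation(x, 4, 4)) > 0))
  expect_error(hill_activation(-1, 5, 2), "x must be")
  expect_error(hill_activation(1, 0, 2), "J must be")
  expect_error(hill_inhibition(1, 5, 0), "n must be")
})

test_that("PleC forcing evaluates the printed two-sinusoid fit", {
  p <- caulo_params()
  expect_equal(plec_level(0),
               80.09 * sin(1.74) + 78.77 * sin(4.85), tolerance = 1e-12)
  expect_equal(plec_level(0), 0.92, tolerance = 0.02)
  # first sine peaks where its argument hits pi/2
  tmax <- (pi / 2 - 1.74) / 0.013
  a1 <- 80.09 * sin(0.013 * tmax + 1.74)
  expect_equal(a1, 80.09, tolerance = 1e-10)
  # periodicity
  tt <- c(0, 17, 93, 140)
  expect_equal(plec_level(tt), plec_level(tt + 2 * pi / 0.013),
               tolerance = 1e-9)
})

test_that("derivatives reproduce hand-evaluated rates at the initial state", {
  p <- caulo_params()
  y <- setNames(as.numeric(caulo_state()), caulo_state_names())
  d <- setNames(caulo_rhs(0, y, p)[[1]], caulo_state_names())
  # simple synthesis-minus-decay protein balances, evaluated by hand
  expect_equal(d[["CcrM"]], 0.0834 * 0.173 - 0.07 * 0.435, tolerance = 1e-12)
  expect_equal(d[["DnaA"]], 0.0787 * 3.154 - 0.07 * 2.638, tolerance = 1e-12)
  expect_equal(d[["CcrM"]], -0.01602, tolerance = 1e-3)
  expect_equal(d[["DnaA"]], 0.06356, tolerance = 1e-3)
  # hemimethylation decay is proportional to h itself
  expect_identical(d[["hCori"]], 0)
  # Z-ring clock off before initiation
  expect_identical(d[["Zring"]], 0)
  with_z <- setNames(caulo_rhs(0, y, p, ks_Zring = 0.011)[[1]],
                     caulo_state_names())
  expect_equal(with_z[["Zring"]], 0.011)
})

test_that("reference RHS, fast RHS and independent oracle agree at random states", {
  p <- caulo_params()
  fast <- caulocycle:::make_rhs(p)
  set.seed(2024)
  for (i in 1:100) {
    y <- random_state()
    t <- stats::runif(1, 0, 400)
    t0 <- stats::runif(1, 0, 150)
    a <- setNames(caulo_rhs(t, y, p, ks_Zring = 0.011, plec_t0 = t0)[[1]],
                  names(y))
    b <- oracle_rhs(t, y, p, ks_Zring = 0.011, plec_t0 = t0)
    f <- setNames(fast(t, y, 0.011, t0)[[1]], names(y))
    expect_equal(a, b, tolerance = 1e-12)
    expect_equal(a, f, tolerance = 1e-12)
  }
})

test_that("RHS rejects invalid states and conserves the CckA pool", {
  p <- caulo_params()
  y <- setNames(as.numeric(caulo_state()), caulo_state_names())
  y_bad <- y; y_bad["CtrA"] <- -0.5
  expect_error(caulo_rhs(0, y_bad, p), "negative")
  y_nan <- y; y_nan["cdG"] <- NaN
  expect_error(caulo_rhs(0, y_nan, p), "non-finite")
  # at a full CckA~P pool the kinase term vanishes, so the rate is <= 0
  y_full <- y; y_full["CckAP"] <- p[["CckA_T"]]
  d <- setNames(caulo_rhs(0, y_full, p)[[1]], names(y))
  expect_lte(d[["CckAP"]], 0)
  # at an empty pool dephosphorylation vanishes, rate >= 0
  y_zero <- y; y_zero["CckAP"] <- 0
  d0 <- setNames(caulo_rhs(0, y_zero, p)[[1]], names(y))
  expect_gte(d0[["CckAP"]], 0)
})

test_that("parameter set enforces its invariants and round-trips to file", {
  p <- caulo_params()
  expect_length(p, 97)   # 86 published constants + forcing, clock and threshold entries
  expect_true(all(p >= 0))
  expect_error(caulo_params(nonsense = 1), "unknown parameter")
  expect_error(caulo_params(ks_Ini = -1), "negative")
  expect_error(caulo_params(Jm_Cori = 0), "> 0")
  # zeroing a proteolysis half-saturation constant is a legitimate variant
  expect_silent(caulo_params(Jd_CpdR = 0))
  tf <- tempfile(fileext = ".tsv")
  write_params(p, tf)
  expect_identical(as.numeric(read_params(tf)), as.numeric(p))
  # packaged default table reproduces the built-in values exactly
  packaged <- system.file("extdata", "params_wildtype.tsv",
                          package = "caulocycle")
  expect_identical(as.numeric(read_params(packaged)), as.numeric(p))
  st <- system.file("extdata", "init_wildtype.tsv", package = "caulocycle")
  expect_identical(as.numeric(read_state(st)), as.numeric(caulo_state()))
})
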