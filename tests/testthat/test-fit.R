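test_that("noiseless forward decays are recovered within 1 percent", {
  irf <- test_irf()
  d <- biexp_forward(400, 2200, 0.6, 0, irf, 48.8, 256, 1e6)
  f <- fit_biexp(d, irf)
  expect_lt(abs(f$tau1 - 400) / 400, 0.01)
  expect_lt(abs(f$tau2 - 2200) / 2200, 0.01)
  expect_lt(abs(f$alpha1 - 0.6) / 0.6, 0.01)
  expect_lt(f$chi_sq_reduced, 0.01)
})

test_that("a mono-exponential decay yields the right mean lifetime", {
  irf <- test_irf()
  d <- biexp_forward(1200, 1200, 1, 0, irf, 48.8, 256, 1e6)
  f <- fit_biexp(d, irf)
  expect_lt(abs(f$tau_m - 1200) / 1200, 0.01)
})

test_that("fit invariants hold across random parameter sets", {
  irf <- test_irf()
  set.seed(7)
  for (i in 1:6) {
    tau1 <- runif(1, 200, 600); tau2 <- tau1 * runif(1, 3, 6)
    a1 <- runif(1, 0.3, 0.9)
    d <- biexp_forward(tau1, tau2, a1, 0, irf, 48.8, 256, 1e5)
    f <- fit_biexp(d, irf)
    expect_identical(f$alpha1 + f$alpha2, 1)            # exact after normalization
    expect_lte(f$tau1, f$tau2)                          # ordering convention
    expect_gte(f$tau_m, min(f$tau1, f$tau2))            # tau_m bounds
    expect_lte(f$tau_m, max(f$tau1, f$tau2))
    expect_lt(abs(f$tau1 - tau1) / tau1, 0.01)          # 1% round trip
    expect_lt(abs(f$tau2 - tau2) / tau2, 0.01)
  }
})

test_that("channel conventions label the short component correctly", {
  irf <- test_irf()
  dn <- biexp_forward(400, 2500, 0.8, 0, irf, 48.8, 128, 1e5, channel = "NADPH")
  df <- biexp_forward(400, 2500, 0.8, 0, irf, 48.8, 128, 1e5, channel = "FAD")
  expect_identical(fit_biexp(dn, irf)$component_labels, c("free", "bound"))
  expect_identical(fit_biexp(df, irf)$component_labels, c("bound", "free"))
})

test_that("low-signal decays are flagged, not fitted", {
  irf <- test_irf()
  d <- biexp_forward(400, 2200, 0.6, 0, irf, 48.8, 128, 50)
  expect_error(fit_biexp(d, irf), class = "omiflim_low_signal")
})

test_that("mean_lifetime computes the weighted mean and validates weights", {
  expect_equal(mean_lifetime(0.7, 400, 0.3, 2500), 1030)
  expect_equal(mean_lifetime(1, 800, 0, 4242), 800)
  expect_equal(mean_lifetime(0.5, 1000, 0.5, 1000), 1000)
  expect_error(mean_lifetime(0.7, 400, 0.2, 2500),
               class = "omiflim_invalid_parameter")
  expect_error(mean_lifetime(0.7, -400, 0.3, 2500),
               class = "omiflim_invalid_parameter")
})

test_that("center-of-mass lifetime maps track a mono-exponential cube", {
  irf <- test_irf()
  curve <- biexp_forward(1400, 1400, 1, 0, irf, 97.65625, 128, 2000)$counts
  cube <- array(rep(curve, 36), dim = c(128, 6, 6))
  tau <- lifetime_map_com(cube, 97.65625, irf, min_photons = 100, bin = 1)
  expect_true(all(abs(tau - 1400) < 40))
  # below the photon floor the map is NaN
  tau2 <- lifetime_map_com(cube * 0, 97.65625, irf, min_photons = 100, bin = 1)
  expect_true(all(is.nan(tau2)))
})
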