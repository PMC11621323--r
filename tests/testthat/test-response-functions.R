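# Composition arithmetic, the two compressibility routes, the critical
# power-law fitter, and the exclusion scan.

test_that("mole fraction converts to weight fraction through the molar masses", {
  expect_equal(signif(mole_to_weight_fraction(0.032), 3), 0.145)
  expect_identical(mole_to_weight_fraction(0), 0)
  expect_identical(mole_to_weight_fraction(1), 1)
})

test_that("number density follows the mean molar mass", {
  expect_equal(signif(number_density(0.997, chi_g = 0), 3), 0.0333)
  expect_equal(signif(number_density(1.261, chi_g = 1), 3), 0.00825)
  expect_equal(number_density(2 * 0.997, 0), 2 * number_density(0.997, 0))
})

test_that("compressibility from S(0) reproduces hand arithmetic", {
  n <- 0.0334; T <- 295
  # ideal-gas limit: S0 = 1 gives exactly 1/(n kB T)
  expect_equal(compressibility_from_S0(1, n, T),
               1 / (n * 1e30 * 1.380649e-23 * T), tolerance = 1e-12)
  k <- compressibility_from_S0(0.060, n, T)
  expect_equal(signif(k, 2), 4.4e-10)
  expect_equal(signif(kappa_to_microbar(k), 2), 44)
  expect_equal(compressibility_from_S0(0.12, n, T), 2 * k, tolerance = 1e-12)
})

test_that("volume-fluctuation estimator is exact on degenerate input", {
  const <- tibble::tibble(volume = rep(2e5, 50))
  expect_identical(kappa_from_volume_fluctuations(const, T = 250), 0)
  # interleaving two copies leaves the estimate unchanged
  vs <- generate_volume_series(3e5, 4e-10, 260, 400, seed = 3)
  twice <- tibble::tibble(volume = as.vector(rbind(vs$volume, vs$volume)))
  expect_equal(kappa_from_volume_fluctuations(twice, T = 260),
               kappa_from_volume_fluctuations(vs), tolerance = 1e-12)
})

test_that("the S(0) and volume-fluctuation compressibility routes agree", {
  kap <- 4.5e-10; T <- 250; n <- 0.0333
  vs <- generate_volume_series(3e5, kap, T, 1e5, seed = 21)
  k_vol <- kappa_from_volume_fluctuations(vs)
  S0 <- kap * (n * 1e30) * 1.380649e-23 * T  # the matched S(0)
  k_s0 <- compressibility_from_S0(S0, n, T)
  expect_lt(abs(k_vol / k_s0 - 1), 0.03)     # ~3 sigma of var() at n = 1e5
})

test_that("power-law fit is an exact round trip on noiseless data", {
  ser <- generate_powerlaw_series(20, 0.36, 224, powerlaw_T_grid)
  f <- fit_powerlaw(ser, "kappa")
  expect_lt(abs(f$amplitude / 20 - 1), 1e-6)
  expect_lt(abs(f$exponent / 0.36 - 1), 1e-6)
  expect_lt(abs(f$T_s / 224 - 1), 1e-6)
  expect_false(f$degenerate)
  expect_gt(f$r_squared, 1 - 1e-10)
})

test_that("power-law fit recovers the exponent from 1% noise on average", {
  res <- purrr::map_dbl(1:30, function(s) {
    ser <- generate_powerlaw_series(20, 0.36, 224, powerlaw_T_grid,
                                    noise_rel = 0.01, seed = 3000 + s)
    fit_powerlaw(ser, "kappa")$exponent
  })
  expect_lt(abs(mean(res) - 0.36), 0.02)
})

test_that("a constant series leaves T_s unidentifiable and is flagged", {
  ser <- tibble::tibble(T = c(240, 250, 260, 270, 280), value = rep(5, 5))
  f <- fit_powerlaw(ser, "kappa")
  expect_true(f$degenerate)
  expect_error(fit_powerlaw(ser[1:3, ], "kappa"),
               class = "aquafluct_error_insufficient_data")
})

test_that("exponent ratio reproduces the Ising benchmark", {
  ising_xi <- list(exponent = 0.6, stderr = c(exponent = 0.01))
  ising_kappa <- list(exponent = 1.2, stderr = c(exponent = 0.02))
  r <- exponent_ratio(ising_xi, ising_kappa)
  expect_equal(r$ratio, 0.5, tolerance = 1e-12)
  expect_gt(r$stderr, 0)
})

test_that("exclusion scan with k = 0 reduces to the plain fit", {
  ser <- generate_powerlaw_series(20, 0.36, 224, powerlaw_T_grid,
                                  noise_rel = 0.01, seed = 11)
  es <- exclusion_scan(ser, k_exclude = 0)
  f <- fit_powerlaw(ser, "kappa")
  expect_equal(es$scan$r_squared[1], f$r_squared, tolerance = 1e-12)
  expect_equal(es$scan$exponent[1], f$exponent, tolerance = 1e-10)
  expect_false(es$deviation_flagged)
})

test_that("exclusion scan flags a Widom-like bend but not a pure power law", {
  Tg <- c(230, powerlaw_T_grid)
  pure <- generate_powerlaw_series(20, 0.36, 224, Tg, noise_rel = 0.005, seed = 5)
  es0 <- exclusion_scan(pure, k_exclude = 1)
  expect_false(es0$deviation_flagged)
  bent <- pure
  bent$value[1] <- bent$value[1] * 0.75 # response saturates below 232 K
  es1 <- exclusion_scan(bent, k_exclude = 1)
  expect_true(es1$deviation_flagged)
  expect_gt(es1$scan$r_squared[2], es1$scan$r_squared[1])
  expect_error(exclusion_scan(pure, k_exclude = 6),
               class = "aquafluct_error_insufficient_data")
})
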