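# g(r) computation, the windowed g(r) -> S(q) transform, and the WAXS
# observables (first-peak position, its derivative maximum, isosbestic point).

test_that("two particles at separation d populate exactly one g(r) bin", {
  cfg <- particle_config(rbind(c(10, 10, 10), c(15, 10, 10)), box = 100)
  rdf <- compute_rdf(cfg, bin_width = 0.02)
  nz <- which(rdf$g > 0)
  expect_length(nz, 1)
  expect_lt(abs(rdf$r[nz] - 5), 0.02)
})

test_that("diamond-lattice g(r) peaks first at the 2.75 A nearest-neighbor shell", {
  cfg <- diamond_config_oracle(3)
  rdf <- compute_rdf(cfg)
  first_nz <- rdf$r[which(rdf$g > 0)[1]]
  expect_lt(abs(first_nz - 2.75), 0.03)
})

test_that("species filtering applies the heavy-atom rule", {
  pos <- matrix(runif(60, 0, 20), ncol = 3)
  cfg <- particle_config(pos, box = 20, species = rep(c("O", "H"), 10))
  rdf <- compute_rdf(cfg) # default excludes H
  expect_identical(attr(rdf, "n_particles"), 10L)
  expect_error(compute_rdf(cfg, species = "N"),
               class = "aquafluct_error_insufficient_data")
})

test_that("window function matches its piecewise closed form and is continuous", {
  r_max <- 10
  expect_identical(window_function(0, r_max), 1)
  expect_identical(window_function(r_max, r_max), 0)
  expect_identical(window_function(2 * r_max, r_max), 0)
  # both branches agree at r_max/3: 1 - 3(1/9) = (3/2)(1 - 2/3 + 1/9) = 2/3
  expect_equal(window_function(r_max / 3, r_max), 2 / 3, tolerance = 1e-12)
  grid <- seq(0, r_max, length.out = 20001)
  w <- window_function(grid, r_max)
  expect_lt(max(abs(diff(w))), 1e-3)             # no jumps on a dense grid
  # branch boundaries: left and right limits agree to 1e-9
  for (b in c(r_max / 3, r_max)) {
    expect_lt(abs(window_function(b - 1e-10, r_max) -
                    window_function(b + 1e-10, r_max)), 1e-9)
  }
  expect_error(window_function(-1, r_max), class = "aquafluct_error_domain")
})

test_that("uncorrelated g(r) transforms to S(q) = 1 at machine precision", {
  rdf <- make_rdf(seq(0.01, 14.99, by = 0.02), g = 1, rho = 0.033, r_max = 15)
  sq <- rdf_to_structure_factor(rdf, c(0.2, 0.7, 1.5, 3))
  expect_equal(sq$S, rep(1, 4), tolerance = 1e-14)
})

test_that("a single delta-like g(r) bin transforms to its closed form", {
  r <- seq(0.01, 14.99, by = 0.02)
  g <- rep(1, length(r))
  i0 <- 250 # interior bin
  g[i0] <- 2
  rho <- 0.03
  rdf <- make_rdf(r, g, rho, r_max = 15)
  q <- c(0.3, 1.1, 2.2)
  sq <- rdf_to_structure_factor(rdf, q)
  r0 <- r[i0]
  closed <- 1 + 4 * pi * rho * window_function(r0, 15) * r0 * 0.02 * sin(q * r0) / q
  expect_equal(sq$S, closed, tolerance = 1e-12)
})

test_that("the transform is linear in g(r) - 1", {
  r <- seq(0.01, 11.99, by = 0.02)
  h <- exp(-(r - 3)^2)
  q <- seq(0.2, 2, by = 0.3)
  s1 <- rdf_to_structure_factor(make_rdf(r, 1 + h, 0.03, 12), q)$S
  s2 <- rdf_to_structure_factor(make_rdf(r, 1 + 2 * h, 0.03, 12), q)$S
  expect_equal(s2 - 1, 2 * (s1 - 1), tolerance = 1e-12)
})

test_that("q = 0 is rejected by the transform", {
  rdf <- make_rdf(seq(0.01, 9.99, 0.02), 1, 0.03, 10)
  expect_error(rdf_to_structure_factor(rdf, c(0, 0.5)),
               class = "aquafluct_error_domain")
})

test_that("Gaussian peak fit recovers an exact peak and absorbs baselines", {
  q <- seq(1.6, 2.0, by = 0.005)
  S <- 2.0 + 0.8 * exp(-(q - 1.80)^2 / (2 * 0.05^2))
  pk <- fit_first_peak(tibble::tibble(q = q, S = S), window = c(1.7, 1.9))
  expect_equal(pk$q1, 1.80, tolerance = 1e-6)
  expect_lt(pk$q1_stderr, 1e-6)
  # adding a constant shifts only the baseline
  pk2 <- fit_first_peak(tibble::tibble(q = q, S = S + 5), window = c(1.7, 1.9))
  expect_equal(pk2$q1, pk$q1, tolerance = 1e-8)
})

test_that("peak fit tolerates noise and linear background", {
  q <- seq(1.6, 2.0, by = 0.005)
  errs <- purrr::map_dbl(1:30, function(s) {
    S <- 1.5 + 0.3 * q + 0.8 * exp(-(q - 1.75)^2 / (2 * 0.05^2)) +
      withr::with_seed(s, rnorm(length(q), 0, 0.01))
    fit_first_peak(tibble::tibble(q = q, S = S), window = c(1.65, 1.95))$q1 - 1.75
  })
  expect_lt(max(abs(errs)), 0.01)
})

test_that("peak fit fails informatively on a monotone curve", {
  q <- seq(1.6, 2.0, by = 0.005)
  expect_error(fit_first_peak(tibble::tibble(q = q, S = 3 - q)),
               class = "aquafluct_error_fit_failure")
  expect_error(fit_first_peak(tibble::tibble(q = q[1:3], S = q[1:3])),
               class = "aquafluct_error_insufficient_data")
})

test_that("dq1/dT maximum is located at the inflection of a tanh profile", {
  Tg <- seq(205, 285, by = 5)
  ser <- tibble::tibble(T = Tg, q1 = 1.7 + 0.05 * tanh((Tg - 231) / 10))
  res <- q1_derivative_maximum(ser)
  expect_true(res$unique)
  expect_lt(abs(res$T_max - 231), 1.5)
})

test_that("a linear q1(T) yields a non-unique derivative maximum", {
  Tg <- seq(210, 280, by = 10)
  res <- q1_derivative_maximum(tibble::tibble(T = Tg, q1 = 1 + 0.001 * Tg))
  expect_false(res$unique)
  expect_true(is.na(res$T_max))
  expect_error(q1_derivative_maximum(tibble::tibble(T = Tg[1:3], q1 = Tg[1:3])),
               class = "aquafluct_error_insufficient_data")
})

test_that("the isosbestic point of a constructed crossing family is recovered", {
  q <- seq(0.2, 1.0, by = 0.005)
  fam <- purrr::map(c(240, 260, 280, 300), function(Tt) {
    tibble::tibble(q = q, S = 0.1 + 0.2 * q + (Tt - 270) * 0.001 * (q - 0.5))
  })
  iso <- find_isosbestic(fam)
  expect_true(iso$unique)
  expect_lt(abs(iso$q_iso - 0.5), 0.002)
  # noisy family crossing at 0.45: recovered within one grid step
  fam_n <- purrr::imap(c(240, 260, 280, 300, 320), function(Tt, i) {
    S <- 0.1 + 0.2 * q + (Tt - 280) * 0.002 * (q - 0.45) +
      withr::with_seed(i, rnorm(length(q), 0, 2e-4))
    tibble::tibble(q = q, S = S)
  })
  iso_n <- find_isosbestic(fam_n)
  expect_lt(abs(iso_n$q_iso - 0.45), 0.01)
})

test_that("degenerate isosbestic inputs are flagged or rejected", {
  q <- seq(0.2, 1.0, by = 0.01)
  same <- replicate(3, tibble::tibble(q = q, S = 0.1 + 0.2 * q), simplify = FALSE)
  iso <- find_isosbestic(same)
  expect_false(iso$unique)
  disjoint <- list(tibble::tibble(q = q, S = q),
                   tibble::tibble(q = q + 2, S = q),
                   tibble::tibble(q = q + 4, S = q))
  expect_error(find_isosbestic(disjoint), class = "aquafluct_error_incompatible_grids")
  expect_error(find_isosbestic(same[1:2]), class = "aquafluct_error_insufficient_data")
})
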