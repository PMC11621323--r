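# Synthetic-data generators. Every generator takes an explicit `seed` and is
# deterministic under it; none touches the caller's RNG state. These stand in
# for the MD and X-ray inputs the pipeline would otherwise require, with known
# ground truth recorded in attributes.

#' Generate an ideal-gas (Poisson) configuration
#'
#' Uniform independent positions in a periodic cubic box: the uncorrelated
#' reference fluid with `g(r) = 1` and `S(q) = 1` in expectation.
#'
#' @param n_particles number of particles (`>= 2`)
#' @param box cubic box edge length, Angstrom
#' @param seed integer seed
#' @return a [particle_config()] with species `"O"`
#' @export
generate_ideal_gas <- function(n_particles, box, seed) {
  n <- check_count(n_particles, "n_particles", min = 2L)
  check_positive(box, "box")
  pos <- with_seed_aq(seed, matrix(runif(3 * n, 0, box), ncol = 3))
  particle_config(pos, box = box, species = "O")
}

#' Generate an equilibrated hard-sphere configuration
#'
#' Random sequential insertion followed by Metropolis relaxation sweeps
#' (single-particle displacements rejected on overlap), giving a fluid with no
#' minimum-image pair distance below `2 * radius`. The attainable packing
#' fraction is capped at 0.45 (insertion becomes impractical beyond it).
#'
#' @param n_particles number of spheres
#' @param box cubic box edge length, Angstrom
#' @param radius hard-sphere radius, Angstrom
#' @param seed integer seed
#' @param n_sweeps Metropolis relaxation sweeps after insertion (default 30)
#' @param max_attempts insertion attempt budget before a placement-failure
#'   error is thrown
#' @return a [particle_config()]
#' @export
generate_hard_sphere <- function(n_particles, box, radius, seed,
                                 n_sweeps = 30L, max_attempts = 2e6) {
  n <- check_count(n_particles, "n_particles", min = 2L)
  check_positive(box, "box")
  check_positive(radius, "radius")
  eta <- n * (4 / 3) * pi * radius^3 / box^3
  if (eta > 0.45) {
    stop_aq(sprintf("packing fraction %.3f exceeds the supported maximum 0.45", eta),
            "invalid_parameter")
  }
  pos <- tryCatch(
    with_seed_aq(seed, .hard_sphere_cpp(n, rep(box, 3), radius,
                                        as.integer(n_sweeps),
                                        0.3 * 2 * radius,
                                        as.integer(max_attempts))),
    error = function(e) {
      if (grepl("placement failure", conditionMessage(e))) {
        stop_aq(conditionMessage(e), "placement_failure")
      }
      stop(e)
    })
  cfg <- particle_config(pos, box = box, species = "O")
  attr(cfg, "packing_fraction") <- eta
  cfg
}

# diamond-cubic lattice constant giving a nearest-neighbor O-O distance of
# 2.75 A (first peak of the water oxygen-oxygen g(r))
.DIAMOND_NN <- 2.75
.DIAMOND_A <- .DIAMOND_NN * 4 / sqrt(3)

# fractional coordinates of the 8 sites of the conventional diamond-cubic cell
diamond_basis <- function() {
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  rbind(fcc, sweep(fcc, 2, c(.25, .25, .25), "+"))
}

# all sites of an nx x ny x nz block of diamond cells (Angstrom)
diamond_lattice <- function(nx, ny, nz, a = .DIAMOND_A) {
  basis <- diamond_basis()
  cells <- expand.grid(i = seq_len(nx) - 1, j = seq_len(ny) - 1, k = seq_len(nz) - 1)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(r) {
    sweep(basis, 2, as.numeric(cells[r, ]), "+")
  }))
  out * a
}

# number density of the HDL-like disordered population (A^-3); slightly above
# the tetrahedral-lattice density so the interstitial region 3.2-3.5 A is
# continuously populated and LSI gap variances stay small
.HDL_DENSITY <- 0.037
.HDL_CORE <- 2.4 # hard-core diameter of the disordered packing, Angstrom

#' Generate a water-like oxygen configuration with controlled LSI structure
#'
#' Builds an oxygen-only configuration mixing two populations: (i) an
#' LDL-like tetrahedral network, realized as a diamond-cubic lattice with
#' nearest-neighbor distance 2.75 Angstrom and Gaussian positional jitter
#' (well-separated first/second shells, hence a large gap in the sorted
#' neighbor distances and high LSI); and (ii) an HDL-like population realized
#' as a dense disordered hard-core packing whose neighbor distances fill the
#' interstitial region between the shells continuously (small, even gaps and
#' hence low LSI). The two populations occupy slabs of one periodic box, so
#' only a thin interface layer is ambiguous. This is a geometric stand-in
#' with controllable LSI bimodality, not a physical water model.
#'
#' @param n_molecules total number of oxygens
#' @param ldl_fraction fraction assigned to the tetrahedral (LDL-like)
#'   population, in `[0, 1]`
#' @param jitter Gaussian positional jitter of lattice sites, Angstrom (`>= 0`)
#' @param seed integer seed
#' @return a [particle_config()]; attribute `ldl_molecules` holds the indices
#'   generated as lattice (LDL-like) sites
#' @export
generate_water_like <- function(n_molecules, ldl_fraction, jitter = 0.05, seed) {
  n <- check_count(n_molecules, "n_molecules", min = 8L)
  check_fraction(ldl_fraction, "ldl_fraction")
  if (!is.numeric(jitter) || jitter < 0) {
    stop_aq("`jitter` must be >= 0", "invalid_parameter")
  }
  n_ldl <- round(ldl_fraction * n)
  n_hdl <- n - n_ldl
  a <- .DIAMOND_A
  rho_ldl <- 8 / a^3
  vol <- n_ldl / rho_ldl + n_hdl / .HDL_DENSITY
  c_xy <- max(2L, round(vol^(1 / 3) / a))
  Lx <- c_xy * a
  with_seed_aq(seed, {
    lattice <- NULL
    z_ldl <- 0
    if (n_ldl > 0) {
      n_layers <- ceiling(n_ldl / (8 * c_xy^2))
      sites <- diamond_lattice(c_xy, c_xy, n_layers, a)
      keep <- sort(sample.int(nrow(sites), n_ldl))
      lattice <- sites[keep, , drop = FALSE] +
        matrix(rnorm(3 * n_ldl, sd = jitter), ncol = 3)
      z_ldl <- n_layers * a
    }
    slab <- 0
    dense <- NULL
    # small vacuum gaps decouple the two slabs (and the periodic wrap) so
    # interface molecules keep the neighbor statistics of their own population
    gap <- if (n_ldl > 0 && n_hdl > 0) 1.8 else 0
    if (n_hdl > 0) {
      slab <- n_hdl / (.HDL_DENSITY * Lx^2)
      dense <- .hard_sphere_cpp(n_hdl, c(Lx, Lx, slab), .HDL_CORE / 2,
                                10L, 0.3 * .HDL_CORE, 2000000L)
      dense[, 3] <- dense[, 3] + z_ldl + gap
    }
    pos <- rbind(lattice, dense)
    cfg <- particle_config(pos, box = c(Lx, Lx, z_ldl + slab + 2 * gap),
                           species = "O")
    attr(cfg, "ldl_molecules") <- seq_len(n_ldl)
    cfg
  })
}

#' Generate a synthetic SAXS structure-factor curve
#'
#' Evaluates the two-component model [saxs_model()] (Percus-Yevick background
#' plus Ornstein-Zernike anomalous component) on a q grid and adds independent
#' additive Gaussian noise of standard deviation `noise_sd`.
#'
#' @param R hard-sphere radius, Angstrom
#' @param eta packing fraction
#' @param SA0 anomalous amplitude at q = 0
#' @param xi correlation length, Angstrom
#' @param q_grid strictly increasing positive wavevectors, inverse Angstrom
#' @param noise_sd additive Gaussian noise standard deviation (dimensionless)
#' @param seed integer seed (ignored when `noise_sd = 0`)
#' @param temperature optional temperature metadata, K
#' @return a tibble with columns `q`, `S`; attributes `truth` (generating
#'   parameters) and `provenance = "synthetic"`
#' @export
generate_saxs_curve <- function(R, eta, SA0, xi, q_grid, noise_sd = 0,
                                seed = 1L, temperature = NA_real_) {
  if (any(diff(q_grid) <= 0) || any(q_grid <= 0)) {
    stop_aq("`q_grid` must be strictly increasing and positive", "invalid_parameter")
  }
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  S <- saxs_model(q_grid, R, eta, SA0, xi)
  if (noise_sd > 0) {
    S <- S + with_seed_aq(seed, rnorm(length(q_grid), sd = noise_sd))
  }
  out <- tibble(q = as.numeric(q_grid), S = S)
  structure(out,
            truth = list(R = R, eta = eta, SA0 = SA0, xi = xi),
            provenance = "synthetic",
            temperature = temperature,
            class = class(out))
}

#' Generate a synthetic critical power-law series
#'
#' `value(T) = amplitude * ((T - T_s) / T_s)^(-exponent)`, optionally with
#' multiplicative relative Gaussian noise. The amplitude is the power-law
#' prefactor (the value at reduced temperature `epsilon = 1`), matching the
#' convention of the fitted divergence law.
#'
#' @param amplitude power-law prefactor, in the units of the series
#' @param exponent critical exponent (`gamma` for compressibility, `nu` for
#'   the correlation length)
#' @param T_s divergence temperature, K; all of `T_grid` must exceed it
#' @param T_grid temperatures, K
#' @param noise_rel relative noise level (e.g. 0.01 for 1 percent)
#' @param seed integer seed
#' @return tibble with columns `T`, `value`; attribute `truth`
#' @export
generate_powerlaw_series <- function(amplitude, exponent, T_s, T_grid,
                                     noise_rel = 0, seed = 1L) {
  check_positive(amplitude, "amplitude")
  check_positive(T_s, "T_s")
  check_positive(noise_rel, "noise_rel", strict = FALSE)
  if (any(T_grid <= T_s)) {
    stop_aq("all temperatures must exceed the divergence temperature T_s", "domain")
  }
  eps <- (T_grid - T_s) / T_s
  value <- amplitude * eps^(-exponent)
  if (noise_rel > 0) {
    value <- value * (1 + with_seed_aq(seed, rnorm(length(T_grid), sd = noise_rel)))
  }
  out <- tibble(T = as.numeric(T_grid), value = value)
  structure(out,
            truth = list(amplitude = amplitude, exponent = exponent, T_s = T_s),
            class = class(out))
}

#' Generate a synthetic NPT volume time series
#'
#' Independent Gaussian volumes with mean `mean_V` and variance
#' `kappa_target * kB * T * mean_V` (the fluctuation-dissipation value), so
#' the volume-fluctuation compressibility estimator recovers `kappa_target`
#' up to sampling error.
#'
#' @param mean_V mean box volume, cubic Angstrom
#' @param kappa_target target isothermal compressibility, 1/Pa (`>= 0`)
#' @param T temperature, K
#' @param n_samples number of samples (`>= 2`)
#' @param seed integer seed
#' @param dt sampling interval, ps (metadata only)
#' @return tibble with columns `time` (ps), `volume` (cubic Angstrom);
#'   attributes `temperature` and `truth`
#' @export
generate_volume_series <- function(mean_V, kappa_target, T, n_samples, seed,
                                   dt = 1) {
  check_positive(mean_V, "mean_V")
  check_positive(kappa_target, "kappa_target", strict = FALSE)
  check_positive(T, "T")
  n <- check_count(n_samples, "n_samples", min = 2L)
  # variance in A^6: kappa [Pa^-1] * kB T [J] * <V> [A^3] * 1e30 [A^3/m^3]
  var_A6 <- kappa_target * .kB * T * mean_V * 1e30
  v <- mean_V + with_seed_aq(seed, rnorm(n, sd = sqrt(var_A6)))
  out <- tibble(time = dt * (seq_len(n) - 1), volume = v)
  structure(out,
            temperature = T,
            truth = list(mean_V = mean_V, kappa_target = kappa_target, T = T),
            class = class(out))
}
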