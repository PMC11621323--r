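#' Radial distribution function of a periodic configuration
#'
#' Minimum-image pair histogram normalized by the ideal-gas shell count at the
#' pair density `(N - 1) / V` of the retained species (exactly unbiased for an
#' uncorrelated configuration at finite N). Following standard X-ray practice
#' only heavy atoms enter by default (hydrogens are excluded: heavy atoms
#' dominate the scattering cross-section), and all retained species are
#' treated as one indistinguishable set; no per-element form-factor weighting
#' is applied (dilute-limit approximation). The histogram extends to
#' `r_max = min(box) / 2`.
#'
#' @param config a [particle_config()]
#' @param exclude species labels to drop (default `"H"`); set `NULL` to keep all
#' @param species if non-NULL, keep only these labels (applied after `exclude`)
#' @param bin_width histogram bin width, Angstrom (default 0.02, fine enough
#'   to resolve the first O-O peak)
#' @return an `rdf_curve` tibble with columns `r` (bin centers, Angstrom) and
#'   `g`; attributes `number_density` (Angstrom^-3), `r_max`, `n_particles`,
#'   `bin_width`
#' @export
compute_rdf <- function(config, exclude = "H", species = NULL, bin_width = 0.02) {
  check_positive(bin_width, "bin_width")
  box <- config_box(config)
  keep <- rep(TRUE, nrow(config))
  if (!is.null(exclude)) keep <- keep & !(config$species %in% exclude)
  if (!is.null(species)) keep <- keep & config$species %in% species
  cfg <- config[keep, , drop = FALSE]
  n <- nrow(cfg)
  if (n < 2L) {
    stop_aq("fewer than 2 particles remain after species filtering",
            "insufficient_data")
  }
  r_max <- min(box) / 2
  counts <- .pair_histogram_cpp(cfg$x, cfg$y, cfg$z, box, bin_width, r_max)
  nbins <- length(counts)
  edges <- bin_width * (0:nbins)
  centers <- (edges[-1] + edges[-(nbins + 1)]) / 2
  rho <- n / prod(box)
  shell <- (4 / 3) * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  # 2 * unordered pair count / N = mean neighbors per particle per bin.
  # The shell norm uses the pair density (N-1)/V, which makes g(r) exactly
  # unbiased for an uncorrelated (Poisson) configuration at finite N.
  g <- (2 * as.numeric(counts) / n) / ((n - 1) / prod(box) * shell)
  out <- tibble(r = centers, g = g)
  structure(out,
            number_density = rho, r_max = r_max,
            n_particles = n, bin_width = bin_width,
            class = c("rdf_curve", class(out)))
}

#' Average radial distribution functions over frames
#'
#' @param rdfs list of `rdf_curve` objects on identical grids (same bin width
#'   and `r_max`)
#' @return an `rdf_curve` with `g` averaged bin-wise and the mean density
#' @export
average_rdf <- function(rdfs) {
  if (length(rdfs) == 0) stop_aq("empty rdf list", "insufficient_data")
  r0 <- rdfs[[1]]$r
  ok <- vapply(rdfs, function(d) length(d$r) == length(r0) &&
                 max(abs(d$r - r0)) < 1e-9, logical(1))
  if (!all(ok)) stop_aq("rdf grids differ between frames", "incompatible_grids")
  g <- rowMeans(vapply(rdfs, function(d) d$g, numeric(length(r0))))
  rho <- mean(vapply(rdfs, function(d) attr(d, "number_density"), numeric(1)))
  out <- tibble(r = r0, g = g)
  structure(out,
            number_density = rho,
            r_max = attr(rdfs[[1]], "r_max"),
            n_particles = attr(rdfs[[1]], "n_particles"),
            bin_width = attr(rdfs[[1]], "bin_width"),
            class = c("rdf_curve", class(out)))
}

#' Truncation window for the g(r) -> S(q) transform
#'
#' Piecewise-quadratic window suppressing truncation ripples of the finite-r
#' Fourier transform: `1 - 3 (r/r_max)^2` for `r < r_max/3`;
#' `(3/2) (1 - r/r_max)^2` (equivalently `(3/2)[1 - 2 r/r_max + (r/r_max)^2]`)
#' for `r_max/3 <= r <= r_max`; `0` beyond. Continuous on `[0, r_max]` with
#' `w(0) = 1`, `w(r_max/3) = 2/3`, `w(r_max) = 0`.
#'
#' @param r radial distance(s), Angstrom (`>= 0`)
#' @param r_max truncation radius, Angstrom
#' @return window weight(s) in `[0, 1]`
#' @export
window_function <- function(r, r_max) {
  if (any(r < 0)) stop_aq("`r` must be >= 0", "domain")
  check_positive(r_max, "r_max")
  u <- r / r_max
  ifelse(u < 1 / 3, 1 - 3 * u^2,
         ifelse(u <= 1, 1.5 * (1 - 2 * u + u^2), 0))
}

#' Structure factor from a radial distribution function
#'
#' Windowed sine transform of the pair correlations,
#' `S(q) = 1 + 4 pi rho int_0^{r_max} w(r) r [g(r) - 1] sin(qr)/q dr`,
#' evaluated by trapezoidal quadrature on the rdf bin centers. The `q = 0`
#' limit is not handled here (extrapolate via the SAXS decomposition instead).
#'
#' @param rdf an `rdf_curve` from [compute_rdf()]
#' @param q_grid strictly positive wavevectors, inverse Angstrom
#' @param temperature optional temperature metadata, K
#' @return tibble with columns `q`, `S`; attributes `provenance = "simulation"`
#'   and `temperature`
#' @export
rdf_to_structure_factor <- function(rdf, q_grid, temperature = NA_real_) {
  if (any(q_grid <= 0)) {
    stop_aq("q = 0 is not supported here; use the SAXS decomposition to extrapolate S(0)",
            "domain")
  }
  rho <- attr(rdf, "number_density")
  r_max <- attr(rdf, "r_max")
  if (is.null(rho) || is.null(r_max)) {
    stop_aq("`rdf` must carry number_density and r_max attributes", "invalid_parameter")
  }
  r <- rdf$r
  w <- window_function(r, r_max)
  base <- w * r * (rdf$g - 1)
  S <- vapply(q_grid, function(q) {
    integrand <- base * sin(q * r) / q
    1 + 4 * pi * rho * trapz(r, integrand)
  }, numeric(1))
  out <- tibble(q = as.numeric(q_grid), S = S)
  structure(out, provenance = "simulation", temperature = temperature,
            class = class(out))
}

# trapezoidal rule on an (increasing) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
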