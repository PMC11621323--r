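# Thermodynamic response functions from fluctuation observables, critical
# power-law fits, and the goodness-of-fit exclusion scan.

#' Mixture composition arithmetic
#'
#' `mole_to_weight_fraction()` converts a solute mole fraction to a weight
#' fraction through the molar masses; `number_density()` converts a mass
#' density to a molecular number density using the mean molar mass
#' `M = chi_g M_g + (1 - chi_g) M_w`.
#'
#' @param chi_g solute (glycerol) mole fraction in `[0, 1]`
#' @param M_g,M_w solute and solvent molar masses, g/mol (defaults: glycerol
#'   92.09382, water 18.01528)
#' @return `mole_to_weight_fraction()`: the weight fraction.
#' @examples
#' mole_to_weight_fraction(0.032) # ~0.145: 3.2 mol% glycerol is 14.5 wt%
#' @export
mole_to_weight_fraction <- function(chi_g, M_g = .M_GLYCEROL, M_w = .M_WATER) {
  check_fraction(chi_g, "chi_g")
  check_positive(M_g, "M_g")
  check_positive(M_w, "M_w")
  chi_g * M_g / (chi_g * M_g + (1 - chi_g) * M_w)
}

#' @rdname mole_to_weight_fraction
#' @param mass_density total mass density, g/cm^3
#' @return `number_density()`: molecules per cubic Angstrom.
#' @examples
#' number_density(0.997, chi_g = 0) # pure water, ~0.0333 molecules / A^3
#' @export
number_density <- function(mass_density, chi_g, M_g = .M_GLYCEROL, M_w = .M_WATER) {
  check_positive(mass_density, "mass_density")
  check_fraction(chi_g, "chi_g")
  M_bar <- chi_g * M_g + (1 - chi_g) * M_w          # g/mol
  (mass_density * .NA_avogadro / M_bar) * 1e-24      # cm^-3 -> A^-3
}

#' Isothermal compressibility from the q -> 0 structure factor
#'
#' `kappa_T = S(0) / (n kB T)` with `n` the molecular number density. Input
#' density is in molecules per cubic Angstrom (converted internally to m^-3);
#' the result is in 1/Pa. Multiply by 1e11 for the conventional display unit
#' of 1e-6 bar^-1 (see [kappa_to_microbar()]).
#'
#' @param S0 structure factor extrapolated to q = 0 (dimensionless)
#' @param n number density, molecules per cubic Angstrom
#' @param T temperature, K
#' @return kappa_T in 1/Pa
#' @export
compressibility_from_S0 <- function(S0, n, T) {
  check_positive(S0, "S0")
  check_positive(n, "n")
  check_positive(T, "T")
  S0 / (n * 1e30 * .kB * T)
}

#' Display conversion of a compressibility to 1e-6 bar^-1
#'
#' @param kappa_pa compressibility in 1/Pa
#' @return the same compressibility expressed in units of 1e-6 bar^-1
#' @export
kappa_to_microbar <- function(kappa_pa) kappa_pa * 1e5 * 1e6

#' Isothermal compressibility from NPT volume fluctuations
#'
#' `kappa_T = <dV^2> / (kB <V> <T>)` with the population (1/N) variance,
#' matching ensemble-average semantics. Volumes are in cubic Angstrom; the
#' result is in 1/Pa. A constant series returns exactly 0.
#'
#' @param series tibble with a `volume` column (cubic Angstrom) and the
#'   temperature either as a `temperature` attribute or via `T`
#' @param T temperature, K (overrides the attribute when given)
#' @return kappa_T in 1/Pa
#' @export
kappa_from_volume_fluctuations <- function(series, T = NULL) {
  stopifnot("volume" %in% names(series))
  v <- series$volume
  if (length(v) < 2L) stop_aq("need at least 2 volume samples", "insufficient_data")
  check_positive(v, "volume")
  if (is.null(T)) T <- attr(series, "temperature")
  check_positive(T, "T")
  var_pop <- mean((v - mean(v))^2)                       # A^6
  var_pop * 1e-60 / (.kB * mean(v) * 1e-30 * T)          # -> Pa^-1
}

#' Fit a critical power law with divergence temperature
#'
#' Nonlinear least squares of `value(T) = amplitude * epsilon^(-exponent)`
#' with `epsilon = (T - T_s) / T_s`, all three parameters free. The fit is
#' performed in linear space with an analytic Jacobian and multi-started over
#' `T_s in {min(T) - 5, min(T) - 15, min(T) - 30}` K (the objective is
#' multimodal in `T_s`). `T_s` is bounded below the lowest fitted
#' temperature. Near-zero exponents leave `T_s` unidentifiable; such fits are
#' flagged degenerate.
#'
#' @param points tibble with columns `T` (K) and `value`, optionally `stderr`
#'   (inverse-variance weights); at least 4 distinct temperatures
#' @param quantity label for the fitted quantity (`"kappa"` or `"xi"`),
#'   metadata only
#' @return a `powerlaw_fit` object: `amplitude`, `exponent`, `T_s`, `stderr`
#'   (named vector), `r_squared`, `residual_norm`, `degenerate`, `quantity`,
#'   `data`
#' @export
fit_powerlaw <- function(points, quantity = c("kappa", "xi")) {
  quantity <- match.arg(quantity)
  stopifnot(all(c("T", "value") %in% names(points)))
  points <- dplyr::arrange(points, .data$T)
  Tv <- points$T
  y <- points$value
  if (length(unique(Tv)) < 4L) {
    stop_aq("need at least 4 distinct temperatures", "insufficient_data")
  }
  w <- if ("stderr" %in% names(points)) 1 / points$stderr^2 else rep(1, length(y))
  sw <- sqrt(w)
  Tmin <- min(Tv)

  model <- function(p) p[1] * ((Tv - p[3]) / p[3])^(-p[2])
  resid_fn <- function(p) sw * (y - model(p))
  jac_fn <- function(p) {
    A <- p[1]; g <- p[2]; Ts <- p[3]
    eps <- (Tv - Ts) / Ts
    m <- A * eps^(-g)
    # d resid / d theta = -sw * d model / d theta
    cbind(-sw * eps^(-g),
          sw * m * log(eps),
          -sw * m * g / eps * (Tv / Ts^2))
  }
  best <- NULL
  for (Ts0 in Tmin - c(5, 15, 30)) {
    eps0 <- (Tv - Ts0) / Ts0
    lf <- stats::lm.fit(cbind(1, log(eps0)), log(pmax(y, 1e-300)))
    start <- c(amplitude = exp(lf$coefficients[[1]]),
               exponent = -lf$coefficients[[2]],
               T_s = Ts0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn, jac = jac_fn,
                         lower = c(1e-300, -20, 0),
                         upper = c(Inf, 20, Tmin - 1e-6),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    stop_aq("power-law fit failed to converge from any start", "fit_failure")
  }
  p <- coef(best)
  V <- tryCatch(vcov_nlslm(best), error = function(e) NULL)
  se <- if (is.null(V)) rep(NA_real_, 3) else sqrt(diag(V))
  names(se) <- c("amplitude", "exponent", "T_s")
  degenerate <- is.null(V) || abs(p[[2]]) < 1e-4 ||
    (!is.na(se[["T_s"]]) && se[["T_s"]] > diff(range(Tv)) * 10)
  ss_tot <- sum(w * (y - weighted.mean(y, w))^2)
  structure(list(
    amplitude = unname(p[[1]]), exponent = unname(p[[2]]), T_s = unname(p[[3]]),
    stderr = se,
    r_squared = 1 - best$deviance / ss_tot,
    residual_norm = sqrt(best$deviance),
    degenerate = degenerate,
    quantity = quantity,
    n = length(y),
    data = tibble(T = Tv, value = y)),
    class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  sym <- if (x$quantity == "kappa") c("kappa_T,0", "gamma") else c("xi_0", "nu")
  cat(sprintf("<powerlaw_fit> %s(T) = %s * ((T - T_s)/T_s)^-%s\n",
              x$quantity, sym[1], sym[2]))
  cat(sprintf("  %s = %.6g +/- %.2g\n", sym[1], x$amplitude, x$stderr[["amplitude"]]))
  cat(sprintf("  %s = %.4f +/- %.4f\n", sym[2], x$exponent, x$stderr[["exponent"]]))
  cat(sprintf("  T_s = %.2f +/- %.2f K\n", x$T_s, x$stderr[["T_s"]]))
  cat(sprintf("  R^2 = %.5f%s\n", x$r_squared,
              if (x$degenerate) "  [degenerate: T_s unidentifiable]" else ""))
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("amplitude", "exponent", "T_s"),
         estimate = c(x$amplitude, x$exponent, x$T_s),
         std.error = unname(x$stderr))
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, residual.norm = x$residual_norm,
         degenerate = x$degenerate, quantity = x$quantity, nobs = x$n)
}

#' Exponent ratio nu / gamma of two power-law fits
#'
#' Computes the ratio of the correlation-length exponent to the
#' compressibility exponent with first-order propagated uncertainty (the
#' Ising benchmark `nu/gamma = 0.63/1.24 ~ 0.5` marks proximity to a critical
#' point).
#'
#' @param fit_xi,fit_kappa `powerlaw_fit` objects (or anything with elements
#'   `exponent` and `stderr[["exponent"]]`)
#' @return one-row tibble with `ratio`, `stderr`
#' @export
exponent_ratio <- function(fit_xi, fit_kappa) {
  nu <- fit_xi$exponent
  ga <- fit_kappa$exponent
  se_nu <- fit_xi$stderr[["exponent"]]
  se_ga <- fit_kappa$stderr[["exponent"]]
  r <- nu / ga
  tibble(ratio = r,
         stderr = abs(r) * sqrt((se_nu / nu)^2 + (se_ga / ga)^2))
}

#' Low-temperature exclusion scan of the power-law fit
#'
#' Refits the power law excluding the `0..k_exclude` lowest-temperature
#' points and reports the goodness of fit per scenario. A Widom-line
#' deviation (the response function bending away from the divergence law as
#' its maximum is approached) is flagged when exclusion improves R^2 by more
#' than `margin`.
#'
#' @param points as in [fit_powerlaw()]
#' @param k_exclude maximum number of lowest-T points to drop; must leave at
#'   least 4 points
#' @param margin R^2 improvement required to flag a deviation (default 0.01)
#' @param quantity forwarded to [fit_powerlaw()]
#' @return an `exclusion_scan` object: `scan` (tibble `k`, `T_min_used`,
#'   `r_squared`, `exponent`, `T_s`), `deviation_flagged`, `best_k`,
#'   `improvement`, `margin`, `fits` (list)
#' @export
exclusion_scan <- function(points, k_exclude = 1L, margin = 0.01,
                           quantity = c("kappa", "xi")) {
  quantity <- match.arg(quantity)
  points <- dplyr::arrange(points, .data$T)
  k_exclude <- check_count(k_exclude, "k_exclude", min = 0L)
  if (nrow(points) - k_exclude < 4L) {
    stop_aq("k_exclude leaves fewer than 4 points", "insufficient_data")
  }
  fits <- purrr::map(0:k_exclude, function(k) {
    fit_powerlaw(points[(k + 1):nrow(points), , drop = FALSE], quantity = quantity)
  })
  scan <- purrr::map2_dfr(0:k_exclude, fits, function(k, f) {
    tibble(k = k, T_min_used = min(f$data$T), r_squared = f$r_squared,
           exponent = f$exponent, T_s = f$T_s)
  })
  improvement <- max(scan$r_squared[-1] - scan$r_squared[1], -Inf)
  flagged <- is.finite(improvement) && improvement > margin
  structure(list(scan = scan,
                 deviation_flagged = flagged,
                 best_k = scan$k[which.max(scan$r_squared)],
                 improvement = if (k_exclude > 0) improvement else 0,
                 margin = margin,
                 fits = fits),
            class = "exclusion_scan")
}

#' @export
print.exclusion_scan <- function(x, ...) {
  cat("<exclusion_scan>\n")
  print(x$scan)
  cat(sprintf("deviation flagged: %s (max R^2 improvement %.4g, margin %.3g)\n",
              x$deviation_flagged, x$improvement, x$margin))
  invisible(x)
}
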