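#' Percus-Yevick hard-sphere structure factor
#'
#' Analytic (Wertheim/Thiele) solution of the Percus-Yevick closure for hard
#' spheres of radius `R` (diameter `2R`) at packing fraction `eta`:
#' `S(q) = 1 / (1 - rho c(q))` with the closed-form direct-correlation
#' function. At `q -> 0` this reduces to the compressibility-route value
#' `S(0) = (1 - eta)^4 / (1 + 2 eta)^2`. To avoid catastrophic cancellation in
#' the trigonometric form, `1/S` is evaluated from its exact series in
#' `(2qR)^2` whenever `2qR < 0.1`; the two branches agree to ~1e-10 at the
#' switchover.
#'
#' @param q wavevector(s), inverse Angstrom (`q >= 0`)
#' @param R hard-sphere radius, Angstrom
#' @param eta packing fraction, `0 <= eta < 0.74`
#' @return S(q), dimensionless, same length as `q`
#' @examples
#' percus_yevick_sq(0, R = 1.78, eta = 0.3) # (0.7)^4 / (1.6)^2
#' @export
percus_yevick_sq <- function(q, R, eta) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0)) {
    stop_aq("`q` must be finite and >= 0", "domain")
  }
  check_positive(R, "R")
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) ||
      eta < 0 || eta >= 0.74) {
    stop_aq("`eta` must lie in [0, 0.74)", "domain")
  }
  if (eta == 0) return(rep(1, length(q)))
  x <- q * 2 * R
  inv <- ifelse(x < 0.1, py_sinv_series(x, eta), py_sinv_trig(x, eta))
  1 / inv
}

# 1/S(q) via the trigonometric Wertheim form, x = q * sigma
py_sinv_trig <- function(x, eta) {
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  ga <- eta * al / 2
  f1 <- (sin(x) - x * cos(x)) / x^3
  f2 <- (2 * x * sin(x) + (2 - x^2) * cos(x) - 2) / x^4
  f3 <- (-x^4 * cos(x) +
           4 * ((3 * x^2 - 6) * cos(x) + (x^3 - 6 * x) * sin(x) + 6)) / x^6
  1 + 24 * eta * (al * f1 + be * f2 + ga * f3)
}

# exact rational series of 1/S(q) about x = 0 (derived symbolically from the
# same Wertheim form), accurate to O(x^8); used below x = 0.1
py_sinv_series <- function(x, eta) {
  den <- 75600 * (1 - eta)^4
  c0 <- (302400 * eta^2 + 302400 * eta + 75600) / den
  c2 <- eta * (-15120 * eta^2 + 41580 * eta - 60480) / den
  c4 <- eta * (189 * eta^3 + 324 * eta^2 - 1944 * eta + 2160) / den
  c6 <- eta * (-6 * eta^3 - 4 * eta^2 + 41 * eta - 40) / den
  c0 + c2 * x^2 + c4 * x^4 + c6 * x^6
}

# d S_PY(0) / d eta, for error propagation in extrapolate_S0()
py_s0_deta <- function(eta) {
  -4 * (1 - eta)^3 / (1 + 2 * eta)^2 - 4 * (1 - eta)^4 / (1 + 2 * eta)^3
}

#' Ornstein-Zernike anomalous structure factor
#'
#' Lorentzian low-q lineshape of critical density fluctuations,
#' `S_A(q) = S_A(0) / (1 + xi^2 q^2)`, with correlation length `xi`.
#'
#' @param q wavevector(s), inverse Angstrom
#' @param SA0 anomalous amplitude at `q = 0` (dimensionless, `>= 0`)
#' @param xi correlation length, Angstrom (`>= 0`)
#' @return S_A(q), same length as `q`
#' @examples
#' ornstein_zernike(1 / 2.5, SA0 = 0.02, xi = 2.5) # = SA0 / 2
#' @export
ornstein_zernike <- function(q, SA0, xi) {
  check_positive(SA0, "SA0", strict = FALSE)
  check_positive(xi, "xi", strict = FALSE)
  SA0 / (1 + xi^2 * q^2)
}

#' Two-component SAXS structure factor model
#'
#' The model used both by the synthetic-curve generator and by [fit_saxs()]:
#' the sum of a normal-liquid Percus-Yevick hard-sphere component and an
#' anomalous Ornstein-Zernike component,
#' `S(q) = S_PY(q; R, eta) + SA0 / (1 + xi^2 q^2)`.
#'
#' @inheritParams percus_yevick_sq
#' @inheritParams ornstein_zernike
#' @return model S(q)
#' @export
saxs_model <- function(q, R, eta, SA0, xi) {
  percus_yevick_sq(q, R, eta) + ornstein_zernike(q, SA0, xi)
}
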