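# WAXS observables: the first-peak position q1(T) of the structure factor,
# its temperature derivative, and the isosbestic point of a curve family.

#' Fit the structure-factor first peak with a Gaussian
#'
#' Nonlinear least-squares fit of `S(q) = baseline + amplitude *
#' exp(-(q - center)^2 / (2 width^2))` inside a fit window (default the WAXS
#' first-peak range 1.7-1.9 inverse Angstrom used for microdroplet data; use
#' 1.7-2.1 when the full peak is accessible). Initialization: center at the
#' argmax inside the window (ties broken toward lower q), width a quarter of
#' the window, baseline the window minimum. A fit whose center escapes the
#' window, with non-positive amplitude, or that fails to converge raises a
#' fit-failure error carrying the initial values and residual norm.
#'
#' @param curve tibble with columns `q`, `S` (optionally `stderr` for weights)
#' @param window numeric length-2 fit window (inverse Angstrom)
#' @return a `peak_position` list: `q1`, `q1_stderr`, `fit_window`,
#'   `gaussian_params` (amplitude, center, width, baseline), `residual_norm`,
#'   and the fit `temperature` if the curve carries one
#' @export
fit_first_peak <- function(curve, window = c(1.7, 1.9)) {
  stopifnot(all(c("q", "S") %in% names(curve)))
  sel <- curve$q >= window[1] & curve$q <= window[2]
  if (sum(sel) < 5L) {
    stop_aq("need at least 5 points inside the fit window", "insufficient_data")
  }
  q <- curve$q[sel]
  S <- curve$S[sel]
  wts <- if ("stderr" %in% names(curve)) 1 / curve$stderr[sel]^2 else rep(1, length(q))
  i0 <- which(S == max(S))[1] # ties toward lower q
  start <- c(amplitude = max(S) - min(S), center = q[i0],
             width = diff(window) / 4, baseline = min(S))
  resid_fn <- function(p) {
    sqrt(wts) * (S - (p[4] + p[1] * exp(-(q - p[2])^2 / (2 * p[3]^2))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       lower = c(-Inf, window[1] - diff(window), 1e-6, -Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 500,
                                                            ftol = 1e-12,
                                                            ptol = 1e-12)),
    error = function(e) NULL)
  fail <- function(reason) {
    stop_aq(paste0("Gaussian peak fit failed: ", reason),
            "fit_failure",
            start = start,
            residual_norm = sqrt(sum(resid_fn(start)^2)))
  }
  if (is.null(fit) || fit$info %in% c(0, 5)) fail("no convergence")
  p <- coef(fit)
  if (p[["center"]] < window[1] || p[["center"]] > window[2]) {
    fail("fitted center outside the window (no peak present)")
  }
  if (p[["amplitude"]] <= 0) fail("non-positive amplitude (no peak present)")
  se <- tryCatch(sqrt(diag(vcov_nlslm(fit))), error = function(e) rep(NA_real_, 4))
  structure(
    list(q1 = unname(p[["center"]]),
         q1_stderr = unname(se[2]),
         fit_window = window,
         gaussian_params = p,
         residual_norm = sqrt(fit$deviance),
         temperature = as.numeric(attr(curve, "temperature"))),
    class = "peak_position")
}

#' @export
print.peak_position <- function(x, ...) {
  cat(sprintf("<peak_position> q1 = %.4f +/- %.4f A^-1 (window %.2f-%.2f)\n",
              x$q1, x$q1_stderr, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

# covariance of an nls.lm fit (sigma^2 (J'J)^-1)
vcov_nlslm <- function(fit) {
  np <- length(coef(fit))
  df <- length(fit$fvec) - np
  s2 <- fit$deviance / max(df, 1)
  s2 * solve(fit$hessian / 2) # hessian = 2 J'J at the optimum (Gauss-Newton)
}

#' Locate the maximum of the temperature derivative dq1/dT
#'
#' Fits a smoothing spline (generalized cross-validation by default) to
#' q1(T), evaluates its derivative on a dense grid, and returns the location
#' of the derivative maximum. A derivative that is flat over the whole range
#' (linear q1(T)) is flagged non-unique.
#'
#' @param series tibble with columns `T` (K, strictly increasing after
#'   sorting) and `q1` (inverse Angstrom); at least 5 temperatures
#' @param spar optional smoothing parameter forwarded to
#'   [stats::smooth.spline()] (default NULL: GCV)
#' @param n_grid dense evaluation grid size
#' @return list with `T_max` (K), `unique` (logical), and `derivative`
#'   (tibble `T`, `dq1_dT`)
#' @export
q1_derivative_maximum <- function(series, spar = NULL, n_grid = 2000L) {
  stopifnot(all(c("T", "q1") %in% names(series)))
  series <- dplyr::arrange(series, .data$T)
  if (nrow(series) < 5L || any(diff(series$T) <= 0)) {
    stop_aq("need >= 5 strictly increasing temperatures", "insufficient_data")
  }
  sp <- if (is.null(spar)) smooth.spline(series$T, series$q1)
        else smooth.spline(series$T, series$q1, spar = spar)
  grid <- seq(min(series$T), max(series$T), length.out = n_grid)
  d1 <- predict(sp, grid, deriv = 1)$y
  rng <- diff(range(d1))
  non_unique <- rng < 1e-8 * max(abs(d1), 1e-12)
  structure(list(
    T_max = if (non_unique) NA_real_ else grid[which.max(d1)],
    unique = !non_unique,
    derivative = tibble(T = grid, dq1_dT = d1)),
    class = "q1_derivative")
}

#' Isosbestic point of a family of structure-factor curves
#'
#' The wavevector at which curves measured at different temperatures
#' intersect, located as the q minimizing the across-curve variance of S(q).
#' Curves are linearly interpolated onto a common dense grid spanning the
#' overlap of their q ranges.
#'
#' @param curves list of at least 3 tibbles with columns `q`, `S`
#' @param n_grid size of the common interpolation grid
#' @return list with `q_iso` (inverse Angstrom), `unique` (FALSE when the
#'   curves are identical so every q minimizes), and `variance` (tibble `q`,
#'   `var_S`)
#' @export
find_isosbestic <- function(curves, n_grid = 1000L) {
  if (length(curves) < 3L) stop_aq("need at least 3 curves", "insufficient_data")
  lo <- max(vapply(curves, function(d) min(d$q), numeric(1)))
  hi <- min(vapply(curves, function(d) max(d$q), numeric(1)))
  if (lo >= hi) stop_aq("curve q ranges do not overlap", "incompatible_grids")
  grid <- seq(lo, hi, length.out = n_grid)
  mat <- vapply(curves, function(d) approx(d$q, d$S, xout = grid)$y,
                numeric(n_grid))
  v <- apply(mat, 1, var)
  degenerate <- max(v) < 1e-12
  structure(list(
    q_iso = if (degenerate) NA_real_ else grid[which.min(v)],
    unique = !degenerate,
    variance = tibble(q = grid, var_S = v)),
    class = "isosbestic")
}
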