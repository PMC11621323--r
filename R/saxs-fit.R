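#' Decompose a SAXS structure factor into normal and anomalous components
#'
#' Weighted nonlinear least-squares fit of the two-component model
#' `S(q) = S_PY(q; R, eta) + SA0 / (1 + xi^2 q^2)` over a low-q window
#' (default 0.15-0.7 inverse Angstrom). The hard-sphere radius is fixed by
#' default at 1.78 Angstrom (temperature-independent); pass `fix_R = NULL` to
#' fit it. The anomalous amplitude is constrained non-negative; the
#' correlation length is bounded in [0, 100] Angstrom and multi-started (3
#' starting values) to avoid the flat valley at `SA0 ~ 0`. When `SA0` is
#' pinned at zero the decomposition is flagged `anomalous_absent` and `xi` is
#' unidentifiable.
#'
#' @param curve tibble with columns `q`, `S` and optionally `stderr`
#'   (per-point standard errors used as inverse-variance weights; weights are
#'   uniform otherwise)
#' @param window numeric length-2 fit window, inverse Angstrom
#' @param fix_R hard-sphere radius to hold fixed (Angstrom), or `NULL` to fit
#' @param xi_starts starting values for the correlation length (multi-start)
#' @param eta_starts starting values for the packing fraction (multi-start;
#'   the PY background and a flat anomalous term trade off in a local
#'   minimum, so the fit is started from a grid of both parameters)
#' @return a `saxs_fit` object with elements `R`, `eta`, `SA0`, `xi`,
#'   `stderr` (named vector), `S0_total`, `S0_stderr`, `fit_window`,
#'   `residual_norm`, `r_squared`, `anomalous_absent`, `R_fixed`, `n_points`
#' @export
fit_saxs <- function(curve, window = c(0.15, 0.7), fix_R = 1.78,
                     xi_starts = c(1, 5, 20), eta_starts = c(0.2, 0.4, 0.6)) {
  stopifnot(all(c("q", "S") %in% names(curve)))
  sel <- curve$q >= window[1] & curve$q <= window[2]
  if (sum(sel) < 8L) {
    stop_aq("need at least 8 points inside the fit window", "insufficient_data")
  }
  q <- curve$q[sel]
  S <- curve$S[sel]
  w <- if ("stderr" %in% names(curve)) 1 / curve$stderr[sel]^2 else rep(1, length(q))
  sw <- sqrt(w)
  free_R <- is.null(fix_R)

  model <- function(p) {
    R <- if (free_R) p[["R"]] else fix_R
    saxs_model(q, R, p[["eta"]], p[["SA0"]], p[["xi"]])
  }
  resid_fn <- function(p) sw * (S - model(p))

  sa0_guess <- max(S[1] - min(S), 1e-3)
  lower <- c(eta = 0, SA0 = 0, xi = 0)
  upper <- c(eta = 0.7399, SA0 = 5, xi = 100)
  if (free_R) {
    lower <- c(lower, R = 0.5)
    upper <- c(upper, R = 5)
  }
  best <- NULL
  for (eta0 in eta_starts) for (xi0 in xi_starts) for (sa0 in unique(c(sa0_guess, 0.05))) {
    start <- c(eta = eta0, SA0 = sa0, xi = xi0)
    if (free_R) start <- c(start, R = 1.78)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 1000, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    stop_aq("SAXS decomposition fit failed to converge from any start",
            "fit_failure", starts = xi_starts)
  }
  p <- coef(best)
  R <- if (free_R) unname(p[["R"]]) else fix_R
  se <- tryCatch(sqrt(diag(vcov_nlslm(best))), error = function(e)
    rep(NA_real_, length(p)))
  names(se) <- names(p)
  anomalous_absent <- p[["SA0"]] < 1e-6
  if (anomalous_absent) se[["xi"]] <- NA_real_

  S_py0 <- percus_yevick_sq(0, R, unname(p[["eta"]]))
  S0 <- unname(p[["SA0"]]) + S_py0
  # propagated stderr: var(SA0) + (dS_PY(0)/deta)^2 var(eta) + 2 cov term
  V <- tryCatch(vcov_nlslm(best), error = function(e) NULL)
  S0_se <- NA_real_
  if (!is.null(V)) {
    gvec <- setNames(numeric(length(p)), names(p))
    gvec["SA0"] <- 1
    gvec["eta"] <- py_s0_deta(unname(p[["eta"]]))
    S0_se <- sqrt(drop(t(gvec) %*% V %*% gvec))
  }
  ss_tot <- sum(w * (S - weighted.mean(S, w))^2)
  structure(list(
    R = R, eta = unname(p[["eta"]]), SA0 = unname(p[["SA0"]]),
    xi = unname(p[["xi"]]),
    stderr = se,
    S0_total = S0, S0_stderr = S0_se,
    fit_window = window,
    residual_norm = sqrt(best$deviance),
    r_squared = 1 - best$deviance / ss_tot,
    anomalous_absent = anomalous_absent,
    R_fixed = !free_R,
    n_points = length(q),
    temperature = as.numeric(attr(curve, "temperature"))),
    class = "saxs_fit")
}

#' @importFrom stats weighted.mean
#' @export
print.saxs_fit <- function(x, ...) {
  cat("<saxs_fit> S(q) = S_PY(q; R, eta) + SA0 / (1 + xi^2 q^2)\n")
  cat(sprintf("  R    = %.4f A %s\n", x$R, if (x$R_fixed) "(fixed)" else
    sprintf("+/- %.4f", x$stderr[["R"]])))
  cat(sprintf("  eta  = %.4f +/- %.4f\n", x$eta, x$stderr[["eta"]]))
  cat(sprintf("  SA0  = %.5f +/- %.5f%s\n", x$SA0, x$stderr[["SA0"]],
              if (x$anomalous_absent) "  [anomalous component absent]" else ""))
  cat(sprintf("  xi   = %.3f A +/- %.3f\n", x$xi, x$stderr[["xi"]]))
  cat(sprintf("  S(0) = %.5f +/- %.5f\n", x$S0_total, x$S0_stderr))
  invisible(x)
}

#' Extrapolate the structure factor to q = 0
#'
#' `S(0) = SA0 + S_PY(0; R, eta)` with the standard error propagated from the
#' fit covariance.
#'
#' @param decomp a `saxs_fit` from [fit_saxs()]
#' @return one-row tibble with columns `S0`, `stderr`
#' @export
extrapolate_S0 <- function(decomp) {
  stopifnot(inherits(decomp, "saxs_fit"))
  tibble(S0 = decomp$S0_total, stderr = decomp$S0_stderr)
}

#' @export
tidy.saxs_fit <- function(x, ...) {
  terms <- c("R", "eta", "SA0", "xi")
  est <- c(x$R, x$eta, x$SA0, x$xi)
  se <- c(if (x$R_fixed) NA_real_ else x$stderr[["R"]],
          x$stderr[["eta"]], x$stderr[["SA0"]], x$stderr[["xi"]])
  tibble(term = terms, estimate = est, std.error = se,
         fixed = c(x$R_fixed, FALSE, FALSE, FALSE))
}

#' @export
glance.saxs_fit <- function(x, ...) {
  tibble(S0 = x$S0_total, S0.stderr = x$S0_stderr,
         r.squared = x$r_squared, residual.norm = x$residual_norm,
         anomalous.absent = x$anomalous_absent, nobs = x$n_points)
}
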