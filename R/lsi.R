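# Local structure index (LSI): variance of the gaps between sorted
# oxygen-oxygen neighbor distances; separates tetrahedrally ordered
# (high-LSI, LDL-like) from interstitial-populated (low-LSI, HDL-like)
# environments.

#' Local structure index per molecule
#'
#' For each oxygen `i`, all minimum-image distances to the other oxygens are
#' sorted ascending; `n_i` counts those inside the O-O cutoff (default 3.7
#' Angstrom); the gap list is `Delta_j = r_(j+1) - r_j` for `j = 1..n_i`, so
#' the last gap spans the cutoff and the first neighbor beyond it
#' participates (the convention of the LSI literature). Then
#' `LSI_i = (1/n_i) sum_j (Delta_j - <Delta>)^2`, in square Angstrom.
#'
#' Molecules with no neighbor inside the cutoff, or whose first neighbor
#' beyond the cutoff is missing or farther than half the box, are excluded
#' and reported via the `skipped` attribute (a warning is emitted). Sorting
#' ties are resolved deterministically (stable sort by particle index).
#'
#' The LSI is sharpest on quenched (inherent-structure) coordinates; thermal
#' configurations give broader distributions. This function operates on the
#' coordinates it is given and performs no minimization.
#'
#' @param config a [particle_config()]
#' @param cutoff O-O neighbor cutoff, Angstrom (default 3.7)
#' @param species species label(s) identifying the oxygens (default `"O"`)
#' @return tibble with columns `molecule` (index among the filtered oxygens),
#'   `n_neighbors`, `lsi` (square Angstrom), `r_next` (first distance beyond
#'   the cutoff); attribute `skipped` holds the indices of excluded molecules
#' @export
lsi_per_molecule <- function(config, cutoff = 3.7, species = "O") {
  check_positive(cutoff, "cutoff")
  cfg <- config[config$species %in% species, , drop = FALSE]
  if (nrow(cfg) < 3L) {
    stop_aq("need at least 3 oxygen atoms", "insufficient_data")
  }
  box <- config_box(config)
  res <- .lsi_cpp(cfg$x, cfg$y, cfg$z, box, cutoff)
  out <- tibble(molecule = seq_len(nrow(cfg)),
                n_neighbors = res$n_neighbors,
                lsi = res$lsi,
                r_next = res$r_next)
  skipped <- out$molecule[is.na(out$lsi)]
  if (length(skipped) > 0) {
    warn(sprintf("%d molecule(s) skipped (no neighbor inside the cutoff, or no valid neighbor beyond it)",
                 length(skipped)))
  }
  keep <- out[!is.na(out$lsi), , drop = FALSE]
  structure(keep, skipped = skipped, cutoff = cutoff, class = class(out))
}

#' LSI of one sorted neighbor-distance list
#'
#' Direct evaluation of the gap-variance definition for a single molecule
#' given its sorted neighbor distances (the last distance supplied must be
#' the first neighbor beyond the cutoff).
#'
#' @param distances sorted ascending neighbor distances, Angstrom; all but
#'   the last must lie inside `cutoff`
#' @param cutoff O-O cutoff, Angstrom
#' @return the LSI value, square Angstrom
#' @examples
#' lsi_from_distances(c(2.8, 2.9, 3.0, 3.5, 4.0)) # gaps .1 .1 .5 .5 -> 0.04
#' @export
lsi_from_distances <- function(distances, cutoff = 3.7) {
  if (is.unsorted(distances, strictly = FALSE)) {
    stop_aq("`distances` must be sorted ascending", "invalid_parameter")
  }
  n_i <- sum(distances < cutoff)
  if (n_i < 1L || n_i >= length(distances)) {
    stop_aq("need >= 1 neighbor inside the cutoff and one beyond it",
            "insufficient_data")
  }
  gaps <- diff(distances)[seq_len(n_i)]
  mean((gaps - mean(gaps))^2)
}

#' Classify HDL-/LDL-like populations from LSI records
#'
#' Molecules with `LSI <= threshold` are HDL-like (disordered, interstitial
#' neighbors present), those above are LDL-like (tetrahedrally ordered). The
#' default threshold 0.114 square Angstrom is the local minimum separating
#' the two modes of the bimodal inherent-structure LSI distribution.
#'
#' @param records tibble from [lsi_per_molecule()] (needs an `lsi` column)
#' @param threshold classification threshold, square Angstrom
#' @param temperature optional temperature metadata, K
#' @return one-row tibble: `T`, `fraction_hdl`, `fraction_ldl`, `threshold`,
#'   `n_molecules` (fractions sum to 1 exactly)
#' @export
classify_populations <- function(records, threshold = 0.114,
                                 temperature = NA_real_) {
  stopifnot("lsi" %in% names(records))
  check_positive(threshold, "threshold")
  lsi <- records$lsi[!is.na(records$lsi)]
  if (length(lsi) < 1L) stop_aq("no LSI records", "insufficient_data")
  f_hdl <- mean(lsi <= threshold)
  tibble(T = as.numeric(temperature),
         fraction_hdl = f_hdl,
         fraction_ldl = 1 - f_hdl,
         threshold = threshold,
         n_molecules = length(lsi))
}

#' Temperature at which the HDL- and LDL-like populations cross
#'
#' Fits a smoothing spline to `fraction_ldl(T)` and returns the temperature
#' at which it crosses 1/2 (equal populations). With multiple roots, the one
#' nearest the median temperature is returned with a multiplicity warning.
#'
#' @param series tibble with columns `T` (K) and `fraction_ldl`, at least 4
#'   temperatures
#' @param n_grid dense evaluation grid size
#' @return `T_cross` in K (scalar)
#' @export
population_crossing <- function(series, n_grid = 4000L) {
  stopifnot(all(c("T", "fraction_ldl") %in% names(series)))
  series <- dplyr::arrange(series, .data$T)
  if (nrow(series) < 4L) stop_aq("need at least 4 temperatures", "insufficient_data")
  sp <- smooth.spline(series$T, series$fraction_ldl)
  grid <- seq(min(series$T), max(series$T), length.out = n_grid)
  f <- predict(sp, grid)$y - 0.5
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    # linear refinement inside the bracketing grid cell
    grid[i] - f[i] * (grid[i + 1] - grid[i]) / (f[i + 1] - f[i])
  }, numeric(1))
  exact <- grid[which(f == 0)]
  roots <- sort(unique(c(roots, exact)))
  if (length(roots) == 0) {
    stop_aq("fraction_ldl never crosses 1/2 within the temperature range",
            "no_crossing")
  }
  if (length(roots) > 1) {
    warn(sprintf("multiple crossings found (%s); returning the one nearest the median temperature",
                 paste(sprintf("%.1f", roots), collapse = ", ")))
  }
  roots[which.min(abs(roots - stats::median(series$T)))]
}
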