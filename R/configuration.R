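#' Particle configurations in periodic orthorhombic boxes
#'
#' A configuration is a tibble with one row per particle (columns `species`,
#' `x`, `y`, `z`; coordinates in Angstrom) carrying the orthorhombic box edge
#' lengths (Angstrom) and an optional temperature (K) as attributes.
#' Coordinates are wrapped into the primary cell `[0, L)` on construction.
#'
#' @param positions numeric matrix or data frame with columns x, y, z (Angstrom)
#' @param box numeric vector of three positive box edge lengths (Angstrom); a
#'   single value is recycled to a cubic box
#' @param species character vector of per-particle labels (recycled)
#' @param temperature optional temperature metadata (K)
#' @return a `particle_config` tibble
#' @examples
#' cfg <- particle_config(matrix(runif(30, 0, 10), ncol = 3), box = 10)
#' config_box(cfg)
#' @export
particle_config <- function(positions, box, species = "O", temperature = NA_real_) {
  pos <- as.matrix(as.data.frame(positions))
  if (ncol(pos) != 3L || !is.numeric(pos) || any(!is.finite(pos))) {
    stop_aq("`positions` must be a finite numeric n x 3 matrix", "invalid_parameter")
  }
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(box) != 3L) {
    stop_aq("`box` must have length 1 or 3 (orthorhombic boxes only)",
            "unsupported_geometry")
  }
  check_positive(box, "box")
  pos <- sweep(pos, 2L, box, function(p, L) p - L * floor(p / L))
  species <- rep_len(as.character(species), nrow(pos))
  out <- tibble(species = species, x = pos[, 1], y = pos[, 2], z = pos[, 3])
  structure(out,
            box = as.numeric(box),
            temperature = as.numeric(temperature),
            class = c("particle_config", class(out)))
}

#' @rdname particle_config
#' @param config a `particle_config`
#' @export
config_box <- function(config) {
  box <- attr(config, "box")
  if (is.null(box)) stop_aq("not a particle_config: box attribute missing", "box_required")
  box
}

#' @rdname particle_config
#' @export
config_temperature <- function(config) as.numeric(attr(config, "temperature"))

# positions as a plain matrix
config_positions <- function(config) {
  cbind(x = config$x, y = config$y, z = config$z)
}

#' @export
print.particle_config <- function(x, ...) {
  box <- attr(x, "box")
  cat(sprintf("<particle_config> %d particles, box %.3f x %.3f x %.3f A",
              nrow(x), box[1], box[2], box[3]))
  tt <- attr(x, "temperature")
  if (length(tt) == 1 && is.finite(tt)) cat(sprintf(", T = %.1f K", tt))
  cat("\n")
  NextMethod()
}

#' All minimum-image pair distances of a configuration
#'
#' Brute-force helper used for small systems and in validation; distances are
#' computed under the minimum-image convention on the orthorhombic box.
#'
#' @param config a [particle_config()]
#' @return numeric vector of the n(n-1)/2 unordered pair distances (Angstrom)
#' @export
min_image_distances <- function(config) {
  pos <- config_positions(config)
  box <- config_box(config)
  n <- nrow(pos)
  if (n < 2L) stop_aq("need at least 2 particles", "insufficient_data")
  out <- numeric(0)
  for (i in seq_len(n - 1L)) {
    d <- sweep(pos[(i + 1L):n, , drop = FALSE], 2L, pos[i, ])
    d <- sweep(d, 2L, box, function(dd, L) dd - L * round(dd / L))
    out <- c(out, sqrt(rowSums(d^2)))
  }
  out
}
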