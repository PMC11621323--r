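# Independent oracle implementations used across the tests. These deliberately
# re-derive quantities by the most direct route available (plain R double
# loops, closed forms, hand-built lattices) so they share no code with the
# package internals they check.

# Brute-force LSI: O(N^2) double loop over molecules, plain R.
lsi_brute_r <- function(config, cutoff = 3.7) {
  pos <- cbind(config$x, config$y, config$z)
  box <- attr(config, "box")
  n <- nrow(pos)
  half <- min(box) / 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- numeric(n - 1)
    k <- 1
    for (j in seq_len(n)) {
      if (j == i) next
      dd <- pos[j, ] - pos[i, ]
      dd <- dd - box * round(dd / box)
      d[k] <- sqrt(sum(dd^2))
      k <- k + 1
    }
    d <- sort(d)
    ni <- sum(d < cutoff)
    if (ni < 1 || ni >= n - 1 || d[ni + 1] > half) next
    gaps <- d[2:(ni + 1)] - d[1:ni]
    out[i] <- mean((gaps - mean(gaps))^2)
  }
  out
}

# Hand-built diamond-cubic oxygen lattice (nearest neighbor 2.75 A),
# m x m x m conventional cells, returned as a particle_config.
diamond_config_oracle <- function(m = 3, nn = 2.75) {
  a <- nn * 4 / sqrt(3)
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  basis <- rbind(fcc, sweep(fcc, 2, c(.25, .25, .25), "+"))
  pos <- NULL
  for (i in 0:(m - 1)) for (j in 0:(m - 1)) for (k in 0:(m - 1)) {
    pos <- rbind(pos, sweep(basis, 2, c(i, j, k), "+"))
  }
  particle_config(pos * a, box = m * a, species = "O")
}

# Build an rdf_curve object by hand (for transform tests with analytic g).
make_rdf <- function(r, g, rho, r_max) {
  out <- tibble::tibble(r = r, g = g)
  structure(out, number_density = rho, r_max = r_max,
            n_particles = NA_integer_, bin_width = r[2] - r[1],
            class = c("rdf_curve", class(out)))
}

# The temperature grid used for the synthetic power-law recovery studies
# (stand-in for the experimental 232-295 K SAXS series).
powerlaw_T_grid <- c(232, 238, 244, 250, 258, 268, 280, 295)
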