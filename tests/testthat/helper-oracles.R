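# Independent oracles and small helpers shared across the suite.

# Naive per-box double-loop scan: the reference box counter.
naive_box_count <- function(mask, sizes) {
  nr <- nrow(mask); nc <- ncol(mask)
  vapply(sizes, function(s) {
    n <- 0L
    for (r0 in seq(1L, nr, by = s)) {
      for (c0 in seq(1L, nc, by = s)) {
        if (any(mask[r0:min(r0 + s - 1L, nr),
                     c0:min(c0 + s - 1L, nc)] > 0)) n <- n + 1L
      }
    }
    n
  }, integer(1))
}

# Closed-form ordinary least squares: slope and intercept of y on x.
ols_closed_form <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Brute-force connected-component count by pixel-pair flood fill,
# independent of the package's graph-based labelling.
brute_component_count <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8L)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  n_comp <- 0L
  for (i in which(mask > 0)) {
    r <- ((i - 1L) %% nr) + 1L; c <- ((i - 1L) %/% nr) + 1L
    if (seen[r, c]) next
    n_comp <- n_comp + 1L
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        r2 <- p[1] + o[1]; c2 <- p[2] + o[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] > 0 && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  n_comp
}

# Small-field generator parameters used by the property suites: the study
# conditions (coverage range, strand geometry) on a quarter-size raster so
# loops over many seeds stay fast.
small_net_params <- function(seed, target = 0.06, noise = 0.002) {
  synthetic_network_params(image_size_px = 320L, rng_seed = seed,
                           target_coverage_frac = target,
                           noise_speckle_frac = noise)
}
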