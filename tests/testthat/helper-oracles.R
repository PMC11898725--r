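# Independent oracles used across test files.

# Exhaustive K-means optimum: minimal SSE over every assignment of the rows
# of Z into k nonempty clusters (feasible up to ~8 points).
brute_force_sse <- function(Z, k = 2) {
  n <- nrow(Z)
  stopifnot(n <= 10)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (i in seq_len(nrow(grid))) {
    lab <- as.integer(grid[i, ])
    if (length(unique(lab)) < k) next
    sse <- 0
    for (j in seq_len(k)) {
      S <- Z[lab == j, , drop = FALSE]
      sse <- sse + sum(sweep(S, 2, colMeans(S))^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# Moments of a Gaussian truncated to [lo, hi] (closed form).
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  m <- mean + sd * (dnorm(a) - dnorm(b)) / Z
  v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                 ((dnorm(a) - dnorm(b)) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Three well-separated Gaussian blobs in the three morphology features.
make_blobs <- function(centers, n = 30, sd = 0.5, seed = 42) {
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    data.frame(length_circumference_cm = rnorm(n, centers[i, 1], sd),
               width_circumference_cm = rnorm(n, centers[i, 2], sd),
               weight_g = rnorm(n, centers[i, 3], sd))
  }))
  cbind(id = seq_len(nrow(out)), out)
}

# class-2 reference values used by several thermal tests
class2_keff <- function() {
  effective_conductivity(0.31, conductivity(4.1, 2), 0.0184)
}
class2_rhocp <- function() {
  (1 - 0.31) * 675.70 * specific_heat(4.1, 2) + 0.31 * 6.8e-3 * 1880
}
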