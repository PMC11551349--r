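# Shared fixtures, all generated in code.

# tiny ideal chessboard simulation for fast end-to-end tests
tiny_chessboard <- function(seed = 1, b = 100L, H = 10L, W = 10L, patch = 5L,
                            n = 3L, scenario = "ideal") {
  sp <- scene_params("chessboard", H = H, W = W, patch = patch,
                     require_all = TRUE)
  generate_raman_dataset(sp, scenario, n = n, b = b, seed = seed)
}

# simplex-vertex fixture: n vertices plus strict convex combinations,
# so the pure-pixel assumption holds exactly
simplex_fixture <- function(n = 3, b = 40, n_mix = 80, seed = 3) {
  set.seed(seed)
  V <- matrix(runif(n * b), n, b) + 1
  C <- matrix(runif(n_mix * n), n_mix, n)
  C <- 0.85 * C / rowSums(C) + 0.05   # strictly interior combinations
  list(d = spectral_dataset(rbind(V, C %*% V)), V = V,
       truth = endmember_set(V))
}

# smooth multi-peak spectrum with structure across the whole axis
smooth_spectrum <- function(b = 200) {
  j <- seq_len(b)
  2 * exp(-(j - b * 0.25)^2 / (2 * 400)) +
    3 * exp(-(j - b * 0.6)^2 / (2 * 900)) +
    1.5 * exp(-(j - b * 0.9)^2 / (2 * 625)) +
    0.5 * sin(j / 30)
}

# brute-force minimal-cost injective assignment of rows to columns
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf; bestp <- NULL
  rec <- function(prefix, avail) {
    if (length(prefix) == n) {
      v <- sum(cost[cbind(seq_len(n), prefix)])
      if (v < best) { best <<- v; bestp <<- prefix }
      return(invisible(NULL))
    }
    for (a in avail) rec(c(prefix, a), setdiff(avail, a))
  }
  rec(integer(0), seq_len(m))
  list(value = best, permutation = bestp)
}
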