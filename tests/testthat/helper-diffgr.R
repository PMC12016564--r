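# Shared test fixtures, built in code.

# symmetric Poisson contact matrix with a mild distance decay
random_cm <- function(n, lambda = 8, resolution = 50000, seed = NULL) {
  gen <- function() {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    m <- matrix(stats::rpois(n * n, lambda / (d + 1)), n, n)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  m <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  contact_matrix(m, resolution = resolution)
}

# independent SCC oracle: literal stratum-by-stratum weighted Pearson
scc_oracle <- function(M1, M2, s, e, max_dist = 1e7) {
  kmax <- min(e - s, floor(max_dist / M1$resolution))
  num <- 0; den <- 0
  for (k in seq_len(kmax)) {
    v1 <- c(); v2 <- c()
    for (i in s:(e - k)) {
      a <- M1$counts[i + 1, i + k + 1]
      b <- M2$counts[i + 1, i + k + 1]
      if (a == 0 && b == 0) next
      v1 <- c(v1, a); v2 <- c(v2, b)
    }
    if (length(v1) < 2) next
    s1 <- stats::sd(v1); s2 <- stats::sd(v2)
    if (s1 <= 0 || s2 <= 0) next
    w <- length(v1) * s1 * s2
    num <- num + w * stats::cor(v1, v2)
    den <- den + w
  }
  if (den > 0) num / den else NA_real_
}

# small synthetic comparison used by several pipeline tests
toy_simulation <- function(n_bins = 480, n_tads = 20, total = 6e5,
                           seed = 7) {
  generate_base_matrix(base_matrix_config(
    n_bins = n_bins, n_tads = n_tads, total_contacts = total,
    min_tad_size = 6, seed = seed))
}
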