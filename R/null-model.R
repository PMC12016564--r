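#' Sample the positions of one random pseudo-TAD
#'
#' A random TAD of length `L` bins is assembled diagonal by diagonal:
#' `L` positions are drawn from the main diagonal, `L - 1` from the first
#' off-diagonal, and so on down to one position from the `(L - 1)`-th
#' off-diagonal, each draw uniform without replacement over the valid
#' positions of that diagonal.  Off-diagonals beyond the genomic-distance
#' cap are not sampled.
#'
#' @param L Pseudo-TAD length in bins.
#' @param n_bins Number of bins of the matrix.
#' @param max_dist Genomic distance cap in bp.
#' @param resolution Bin width in bp.
#' @return A tibble of sampled positions with columns `i`, `j` (0-based)
#'   and `d = j - i`.
#' @export
sample_null_tad <- function(L, n_bins, max_dist = 1e7, resolution = 50000) {
  if (L < 1 || L > n_bins) stop("`L` must be in [1, n_bins]")
  dmax <- min(L - 1, floor(max_dist / resolution))
  rows <- purrr::map(0:dmax, function(d) {
    i <- sort(sample.int(n_bins - d, L - d)) - 1L
    tibble::tibble(i = i, j = i + d, d = d)
  })
  dplyr::bind_rows(rows)
}

#' Permutation null distribution of the SCC for a given TAD size
#'
#' Repeats the random pseudo-TAD construction of [sample_null_tad()]
#' `N` times, extracts the sampled positions from both (identically
#' preprocessed) matrices, and computes each pseudo-TAD pair's SCC with
#' the sampled positions stratified by diagonal (distance-0 positions are
#' drawn but, as in [scc()], do not form a stratum).  Pseudo-TADs whose
#' SCC is undefined (no stratum with positive weight) are dropped and `N`
#' decremented.
#'
#' @param M1,M2 [contact_matrix] objects, preprocessed identically.
#' @param L TAD size in bins.
#' @param N Number of permutations (default 2000).
#' @param max_dist Genomic distance cap in bp.
#' @param seed Optional integer seed giving a reproducible draw without
#'   touching the caller's RNG state.
#' @param engine `"cpp"` (default) for the compiled sampler or `"r"` for
#'   the plain-R reference implementation; both consume R's RNG.
#' @return An object of class `null_distribution`: list with
#'   `length_bins`, `values` (sorted SCC draws), `N`.
#' @export
null_scc_distribution <- function(M1, M2, L, N = 2000, max_dist = 1e7,
                                  seed = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_pair(M1, M2)
  if (L < 2 || L > M1$n_bins) stop("`L` must be in [2, n_bins]")
  draw <- if (engine == "cpp") {
    dmax <- min(L - 1, floor(max_dist / M1$resolution))
    function() cpp_null_scc_draws(M1$counts, M2$counts, L, N, dmax)
  } else {
    function() null_scc_draws(M1, M2, L, N, max_dist)
  }
  vals <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  vals <- vals[is.finite(vals)]
  if (length(vals) < 100) {
    stop("fewer than 100 defined null SCC values at size ", L,
         "; use a larger TAD size or denser data")
  }
  structure(list(length_bins = L, values = sort(vals), N = length(vals)),
            class = "null_distribution")
}

# Vectorized engine: all N pseudo-TADs at once, one diagonal at a time.
# For each diagonal d the per-permutation Pearson moments are accumulated
# columnwise; the weight N_k * sd1 * sd2 times rho_k reduces to N_k * cov,
# so only covariances and variances are needed.
null_scc_draws <- function(M1, M2, L, N, max_dist) {
  n <- M1$n_bins
  dmax <- min(L - 1, floor(max_dist / M1$resolution))
  num <- numeric(N)
  den <- numeric(N)
  for (d in 0:dmax) {
    m <- L - d            # positions per pseudo-TAD on this diagonal
    avail <- n - d
    idx <- if (m == avail) {
      matrix(rep(seq_len(avail), N), avail, N)
    } else {
      vapply(seq_len(N), function(p) sample.int(avail, m), integer(m))
    }
    if (d == 0) next      # drawn for procedure fidelity, not a stratum
    i <- as.vector(idx)
    lin <- i + (i + d - 1) * n   # column-major linear index of (i, i+d)
    V1 <- matrix(M1$counts[lin], m, N)
    V2 <- matrix(M2$counts[lin], m, N)
    keep <- (V1 != 0) | (V2 != 0)
    nk <- .colSums(keep, m, N)
    V1[!keep] <- 0
    V2[!keep] <- 0
    s1 <- .colSums(V1, m, N)
    s2 <- .colSums(V2, m, N)
    s11 <- .colSums(V1 * V1, m, N)
    s22 <- .colSums(V2 * V2, m, N)
    s12 <- .colSums(V1 * V2, m, N)
    ok <- nk >= 2
    nk2 <- ifelse(ok, nk, 2)  # avoid 0/0; masked out below
    cv <- (s12 - s1 * s2 / nk2) / (nk2 - 1)
    v1 <- pmax((s11 - s1 * s1 / nk2) / (nk2 - 1), 0)
    v2 <- pmax((s22 - s2 * s2 / nk2) / (nk2 - 1), 0)
    w_ok <- ok & v1 > 0 & v2 > 0
    num <- num + ifelse(w_ok, nk * cv, 0)
    den <- den + ifelse(w_ok, nk * sqrt(v1) * sqrt(v2), 0)
  }
  out <- rep(NA_real_, N)
  pos <- den > 0
  out[pos] <- num[pos] / den[pos]
  # clamp floating-point overshoot of perfectly correlated strata
  pmin(pmax(out, -1), 1)
}

#' Permutation p-value of an observed SCC
#'
#' The p-value is the fraction of null SCC draws strictly below the
#' observed value: a low SCC relative to the null gives a small p and
#' marks a candidate differential TAD.  With `add_one = TRUE` the
#' `(r + 1) / (N + 1)` convention is used instead, which avoids exact
#' zeros for downstream consumers that cannot handle them.
#'
#' @param rho_obs Observed SCC.
#' @param null A `null_distribution`.
#' @param add_one Use the add-one p-value convention (default `FALSE`).
#' @return A p-value in `[0, 1]`, or `NA` if `rho_obs` is `NA`.
#' @export
permutation_pvalue <- function(rho_obs, null, add_one = FALSE) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$N < 100) stop("null distribution has fewer than 100 draws")
  if (is.na(rho_obs)) return(NA_real_)
  r <- sum(null$values < rho_obs)
  if (add_one) (r + 1) / (null$N + 1) else r / null$N
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control over the family of all
#' tested potential TADs of one chromosome-pair comparison.
#'
#' @param pvals Numeric vector of p-values (`NA`s are passed through).
#' @return Vector of q-values of the same length.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stats::p.adjust(pvals, method = "BH")
}

#' Similarity filter on permutation p-values
#'
#' Between highly similar samples (e.g. biological replicates) the null
#' SCCs are themselves high, so mildly lower — but still high — observed
#' SCCs can reach small p-values.  The filter resets the p-value of any
#' nominally significant TAD whose observed SCC exceeds the similarity
#' threshold `theta` to 0.5:
#' `p_adj = 0.5` if `p < alpha` and `rho > theta`, else `p`.
#'
#' @param p P-value(s).
#' @param rho Observed SCC value(s), recycled against `p`.
#' @param alpha Significance level (default 0.05).
#' @param theta Similarity threshold in (0, 1); 0.85 separates
#'   non-replicates from biological/pseudo-replicates in whole-chromosome
#'   comparisons.
#' @return Filtered p-value(s).
#' @export
theta_filter <- function(p, rho, alpha = 0.05, theta = 0.85) {
  if (theta <= 0 || theta >= 1) stop("`theta` must be in (0, 1)")
  ifelse(!is.na(p) & !is.na(rho) & p < alpha & rho > theta, 0.5, p)
}

#' Automatic similarity threshold from replicate structure
#'
#' Sets `theta` to the midpoint between the typical null SCC of
#' non-replicate pairs and that of biological/pseudo-replicate pairs:
#' each group contributes the mean (over its pairs) of the
#' `alpha`-quantile of the pair's null SCC distribution at TAD size `L`.
#'
#' @param nonrep_pairs List of `list(M1, M2)` non-replicate matrix pairs.
#' @param rep_pairs List of `list(M1, M2)` biological or pseudo-replicate
#'   pairs.
#' @param L TAD size in bins at which the null is sampled.
#' @param alpha Quantile level (default 0.05).
#' @param N Permutations per pair (default 2000).
#' @param max_dist Genomic distance cap in bp.
#' @param seed Optional seed for reproducible draws.
#' @return The threshold `theta`.
#' @export
auto_theta <- function(nonrep_pairs, rep_pairs, L, alpha = 0.05, N = 2000,
                       max_dist = 1e7, seed = NULL) {
  if (!length(nonrep_pairs) || !length(rep_pairs)) {
    stop("need at least one pair in each group")
  }
  for (a in nonrep_pairs) for (b in rep_pairs) {
    if (identical(a, b)) stop("a pair appears in both groups")
  }
  qt <- function(pair, k) {
    nd <- null_scc_distribution(pair[[1]], pair[[2]], L, N = N,
                                max_dist = max_dist,
                                seed = if (is.null(seed)) NULL else seed + k)
    stats::quantile(nd$values, alpha, names = FALSE)
  }
  q_nr <- mean(purrr::imap_dbl(nonrep_pairs, function(p, k) qt(p, k)))
  q_br <- mean(purrr::imap_dbl(rep_pairs, function(p, k) qt(p, 1000 + k)))
  (q_nr + q_br) / 2
}

#' Fit a smooth threshold curve through per-size null quantiles
#'
#' For the permutation speed-up, exact nulls are sampled only at a subset
#' of TAD sizes and a smoothing spline is fitted through the
#' `(size, alpha-quantile)` points.  A TAD of an untested size is called
#' significant at level `alpha` when its observed SCC falls below the
#' fitted threshold at that size.  The returned function evaluates the
#' curve and yields `NA` outside the fitted size range, signalling the
#' caller to fall back to exact permutation there.
#'
#' @param sizes Integer vector of TAD sizes (>= 5 distinct values).
#' @param distributions List of `null_distribution` objects matching
#'   `sizes`.
#' @param alpha Quantile level.
#' @return A function `threshold(size)`; attributes `range` (fitted size
#'   range) and `knots` (the input points) are attached.
#' @export
fit_null_quantile_curve <- function(sizes, distributions, alpha = 0.05) {
  if (length(sizes) != length(distributions)) {
    stop("`sizes` and `distributions` differ in length")
  }
  if (length(unique(sizes)) < 5) {
    stop("need at least 5 distinct sizes to fit the threshold curve")
  }
  q <- purrr::map_dbl(distributions,
                      ~ stats::quantile(.x$values, alpha, names = FALSE))
  fit <- stats::smooth.spline(sizes, q, df = min(length(unique(sizes)), 4))
  rng <- range(sizes)
  f <- function(size) {
    out <- stats::predict(fit, as.numeric(size))$y
    out[size < rng[1] | size > rng[2]] <- NA_real_
    out
  }
  attr(f, "range") <- rng
  attr(f, "knots") <- data.frame(size = sizes, quantile = q)
  f
}

# Approximate null CDF at an arbitrary size by interpolating empirical
# quantile curves fitted at the knot sizes over a probability grid.
# Returns a function p(rho, size) used by the pipeline's speed-up mode.
fit_null_cdf_surface <- function(sizes, distributions,
                                 probs = seq(0.005, 0.995, by = 0.005)) {
  qmat <- vapply(distributions,
                 function(d) stats::quantile(d$values, probs, names = FALSE),
                 numeric(length(probs)))  # probs x sizes
  fits <- apply(qmat, 1L, function(qrow) {
    stats::smooth.spline(sizes, qrow, df = min(length(unique(sizes)), 4))
  })
  rng <- range(sizes)
  function(rho, size) {
    if (size < rng[1] || size > rng[2]) return(NA_real_)
    qs <- vapply(fits, function(f) stats::predict(f, as.numeric(size))$y,
                 numeric(1))
    qs <- cummax(qs)  # enforce a valid (monotone) quantile function
    if (rho <= qs[1]) return(0)
    if (rho > qs[length(qs)]) return(1)
    stats::approx(qs, probs, xout = rho, ties = "ordered")$y
  }
}
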