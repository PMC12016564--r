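#' Stratify two contact maps over a bin interval by genomic distance
#'
#' Collects, for each genomic distance `k` (in bins) from 1 up to the
#' smaller of the interval span and `max_dist`, the paired contact values
#' `(M1[i, i + k], M2[i, i + k])` with both loci inside the interval.
#' Pairs where both samples record zero contacts are excluded: in sparse
#' maps they carry no signal and would inflate stratum correlations.  The
#' main diagonal (distance 0) is not a stratum.
#'
#' @param M1,M2 [contact_matrix] objects on the same bins.
#' @param start_bin,end_bin Inclusive 0-based bin interval.
#' @param max_dist Maximum genomic distance in bp (default 10 Mb); strata
#'   beyond it are not formed because distal contacts are sparse and
#'   stochastic.
#' @return A tibble with one row per stratum: `k`, `n_pairs`, and
#'   list-columns `v1`, `v2` of the retained paired values.
#' @export
scc_stratify <- function(M1, M2, start_bin, end_bin, max_dist = 1e7) {
  check_pair(M1, M2)
  if (start_bin >= end_bin) stop("`start_bin` must be < `end_bin`")
  if (start_bin < 0 || end_bin >= M1$n_bins) stop("interval out of range")
  kmax <- min(end_bin - start_bin, floor(max_dist / M1$resolution))
  strata <- purrr::map(seq_len(kmax), function(k) {
    i <- (start_bin:(end_bin - k)) + 1L  # 1-based row indices
    idx <- cbind(i, i + k)
    v1 <- M1$counts[idx]
    v2 <- M2$counts[idx]
    keep <- !(v1 == 0 & v2 == 0)
    tibble::tibble(k = k, n_pairs = sum(keep),
                   v1 = list(v1[keep]), v2 = list(v2[keep]))
  })
  dplyr::bind_rows(strata)
}

#' Stratum-adjusted correlation coefficient over a bin interval
#'
#' The SCC removes the distance-decay confound of contact maps by
#' correlating the two samples within each genomic-distance stratum and
#' averaging the per-stratum Pearson correlations \eqn{\rho_k} with
#' weights \eqn{N_k r_{2k}}, where \eqn{N_k} is the number of retained
#' locus pairs of stratum \eqn{k} and \eqn{r_{2k}} the product of the two
#' samples' stratum standard deviations:
#' \deqn{\rho = \frac{\sum_k N_k r_{2k} \rho_k}{\sum_k N_k r_{2k}}.}
#' Strata with fewer than two retained pairs or with zero variance in
#' either sample get weight zero.  When no stratum qualifies the SCC is
#' undefined and returned as `NA` with `defined = FALSE`.
#'
#' @inheritParams scc_stratify
#' @return A one-row tibble: `rho`, `defined`, `n_strata_used`,
#'   `total_pairs`.
#' @examples
#' m <- matrix(rpois(64, 10), 8); m <- m + t(m)
#' cm <- contact_matrix(m, resolution = 50000)
#' scc(cm, cm, 0, 7)$rho  # identical maps give SCC 1
#' @export
scc <- function(M1, M2, start_bin, end_bin, max_dist = 1e7) {
  check_pair(M1, M2)
  if (start_bin >= end_bin) stop("`start_bin` must be < `end_bin`")
  if (start_bin < 0 || end_bin >= M1$n_bins) stop("interval out of range")
  kmax <- min(end_bin - start_bin, floor(max_dist / M1$resolution))
  n <- M1$n_bins
  num <- 0; den <- 0; used <- 0L; pairs <- 0L
  for (k in seq_len(kmax)) {
    i <- (start_bin:(end_bin - k)) + 1L
    lin <- i + (i + k - 1L) * n
    v1 <- M1$counts[lin]
    v2 <- M2$counts[lin]
    keep <- v1 != 0 | v2 != 0
    v1 <- v1[keep]; v2 <- v2[keep]
    nk <- length(v1)
    pairs <- pairs + nk
    if (nk < 2) next
    s1 <- stats::sd(v1); s2 <- stats::sd(v2)
    if (s1 <= 0 || s2 <= 0) next
    w <- nk * s1 * s2
    num <- num + w * stats::cor(v1, v2)
    den <- den + w
    used <- used + 1L
  }
  tibble::tibble(
    rho = if (den > 0) num / den else NA_real_,
    defined = den > 0,
    n_strata_used = used,
    total_pairs = pairs
  )
}

check_pair <- function(M1, M2) {
  stopifnot(inherits(M1, "contact_matrix"), inherits(M2, "contact_matrix"))
  if (M1$n_bins != M2$n_bins) stop("matrices differ in bin count")
  if (M1$resolution != M2$resolution) stop("matrices differ in resolution")
  invisible(TRUE)
}
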