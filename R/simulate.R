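#' Configuration of the synthetic base contact matrix
#'
#' The generator emulates a deeply sequenced intra-chromosomal Hi-C map
#' with block-TAD structure: expected contacts decay with genomic
#' distance as a power law, pairs inside the same TAD are enriched by a
#' constant factor, and observed counts are Poisson draws around the
#' expectation.  The defaults emulate a 50-kb-resolution human chromosome
#' 1 map partitioned into 189 TADs of mean size 24 bins (1.2 Mb).
#'
#' @param n_bins Number of bins (default 4990).
#' @param resolution Bin width in bp (default 50 kb).
#' @param n_tads Number of TADs tiling the chromosome (default 189).
#' @param decay_exponent Exponent of the distance decay
#'   `(|i - j| + 1)^decay_exponent` (default -1).
#' @param intra_tad_enrichment Multiplicative contact enrichment of
#'   same-TAD pairs (default 3).
#' @param total_contacts Expected total contact count over the upper
#'   triangle (default 2e7).
#' @param min_tad_size Smallest TAD size drawn, in bins (default 6).
#' @param tad_size_cv Coefficient of variation of the drawn TAD sizes
#'   (default 1/3).
#' @param bias_sd Log-scale standard deviation of the multiplicative
#'   per-bin coverage biases (default 0.4, giving the 30-50% bin-level
#'   coverage variation typical of real maps; balancing removes these).
#' @param structure_sd Log-scale standard deviation, at one-bin genomic
#'   distance, of the locus-pair structure factors (default 0.4).  These
#'   fixed pairwise factors model loops and other fine-scale structure
#'   shared by replicates of the same condition; without them every
#'   same-distance intra-TAD pair would have the same expected count and
#'   replicates would decorrelate within TADs, unlike any real contact
#'   map.  The log-sd grows with distance `d` as `structure_sd * sqrt(d)`
#'   up to the ~1-Mb loop scale: relative dispersion in real maps rises
#'   with genomic distance as dense near-diagonal decay gives way to
#'   bursty loop and speckle enrichment.
#' @param seed Optional seed for a reproducible matrix.
#' @return A list of class `base_matrix_config`.
#' @export
base_matrix_config <- function(n_bins = 4990, resolution = 50000,
                               n_tads = 189, decay_exponent = -1,
                               intra_tad_enrichment = 3,
                               total_contacts = 2e7, min_tad_size = 6,
                               tad_size_cv = 1 / 3, bias_sd = 0.4,
                               structure_sd = 0.4, seed = NULL) {
  if (decay_exponent >= 0) stop("`decay_exponent` must be negative")
  if (intra_tad_enrichment <= 1) stop("`intra_tad_enrichment` must be > 1")
  if (n_tads * min_tad_size > n_bins) {
    stop("cannot fit ", n_tads, " TADs of >= ", min_tad_size,
         " bins into ", n_bins, " bins")
  }
  structure(list(n_bins = as.integer(n_bins), resolution = resolution,
                 n_tads = as.integer(n_tads),
                 decay_exponent = decay_exponent,
                 intra_tad_enrichment = intra_tad_enrichment,
                 total_contacts = total_contacts,
                 min_tad_size = as.integer(min_tad_size),
                 tad_size_cv = tad_size_cv, bias_sd = bias_sd,
                 structure_sd = structure_sd, seed = seed),
            class = "base_matrix_config")
}

#' Generate a synthetic base contact matrix with known TADs
#'
#' @param cfg A [base_matrix_config].
#' @return A list with elements `matrix` (a [contact_matrix]),
#'   `boundaries` (a [boundary_set] of the true TAD partition), `tads`
#'   (tibble of TAD bin intervals) and `config`.
#' @examples
#' sim <- generate_base_matrix(base_matrix_config(n_bins = 100, n_tads = 5,
#'   total_contacts = 1e5, seed = 1))
#' sim$matrix
#' @export
generate_base_matrix <- function(cfg = base_matrix_config()) {
  stopifnot(inherits(cfg, "base_matrix_config"))
  gen <- function() {
    sizes <- draw_tad_sizes(cfg)
    ends <- cumsum(sizes) - 1L           # last bin of each TAD, 0-based
    tad_id <- rep(seq_along(sizes), sizes)
    n <- cfg$n_bins
    # per-diagonal expected-sum bookkeeping to hit `total_contacts`
    d_all <- 0:(n - 1L)
    base_d <- (d_all + 1)^cfg$decay_exponent
    intra_d <- vapply(d_all, function(d) sum(pmax(sizes - d, 0L)),
                      numeric(1))
    exp_sum <- sum(base_d * ((n - d_all) +
                               (cfg$intra_tad_enrichment - 1) * intra_d))
    c0 <- cfg$total_contacts / exp_sum
    # multiplicative per-bin coverage biases (mean 1), as in real maps
    bias <- stats::rlnorm(n, 0, cfg$bias_sd)
    bias <- bias / mean(bias)
    # locus-pair structure factors (mean 1): loops and sub-TAD features
    # extend over several bins, so the log-field is spatially correlated
    # (white noise box-averaged over a 5x5 window, rescaled to unit
    # standard deviation) rather than independent per entry; its log-sd
    # grows with genomic distance as sqrt(d), saturating at the ~1-Mb
    # loop scale, because near-diagonal contacts are dense and smooth
    # while distal ones are dominated by bursty loop/speckle enrichment
    z <- matrix(stats::rnorm(n * n), n, n)
    z <- box_mean((z + t(z)) / sqrt(2), 2L)
    z <- z / stats::sd(z)
    d_sat <- ceiling(1e6 / cfg$resolution)
    m <- matrix(0, n, n)
    for (d in d_all) {
      i <- seq_len(n - d)
      same <- tad_id[i] == tad_id[i + d]
      s_d <- cfg$structure_sd * sqrt(min(d, d_sat))
      struct_v <- exp(z[cbind(i, i + d)] * s_d - s_d^2 / 2)
      mu <- c0 * base_d[d + 1L] *
        ifelse(same, cfg$intra_tad_enrichment, 1) *
        bias[i] * bias[i + d] * struct_v
      x <- stats::rpois(n - d, mu)
      m[cbind(i, i + d)] <- x
      m[cbind(i + d, i)] <- x
    }
    list(m = m, ends = ends, sizes = sizes)
  }
  out <- if (is.null(cfg$seed)) gen() else withr::with_seed(cfg$seed, gen())
  tads <- tibble::tibble(
    start_bin = c(0L, utils::head(out$ends, -1L) + 1L),
    end_bin = out$ends,
    size = out$sizes)
  list(matrix = contact_matrix(out$m, resolution = cfg$resolution),
       boundaries = boundary_set(out$ends, sample_id = "truth"),
       tads = tads, config = cfg)
}

# TAD sizes around the target mean, truncated below, adjusted to tile the
# chromosome exactly
draw_tad_sizes <- function(cfg) {
  mean_size <- cfg$n_bins / cfg$n_tads
  sizes <- pmax(cfg$min_tad_size,
                round(stats::rnorm(cfg$n_tads, mean_size,
                                   cfg$tad_size_cv * mean_size)))
  diff <- cfg$n_bins - sum(sizes)
  while (diff != 0) {
    k <- sample.int(cfg$n_tads, 1)
    step <- sign(diff)
    if (sizes[k] + step >= cfg$min_tad_size) {
      sizes[k] <- sizes[k] + step
      diff <- diff - step
    }
  }
  as.integer(sizes)
}

tads_from_boundaries <- function(b, n_bins) {
  ends <- sort(unique(c(b$bins, n_bins - 1L)))
  tibble::tibble(start_bin = c(0L, utils::head(ends, -1L) + 1L),
                 end_bin = ends)
}

#' Alter a subset of TADs by within-diagonal count substitution
#'
#' Emulates single-TAD differences: a fraction `prop_tads` of the TADs is
#' selected as truly differential, and within each selected TAD a
#' fraction `prop_alter` of the intra-TAD bin pairs is replaced by the
#' count observed at a uniformly drawn position of the *same* diagonal
#' anywhere in the matrix.  Substituting within the diagonal preserves
#' each distance's marginal count distribution while destroying the local
#' structure.  All entries outside the selected TADs are untouched.
#'
#' @param M A [contact_matrix] (the original, which is also the source of
#'   the substituted values).
#' @param tads A [boundary_set] with the TAD partition of `M`.
#' @param prop_tads Fraction of TADs to alter (default 0.5).
#' @param prop_alter Fraction of intra-TAD entries substituted within
#'   each altered TAD (default 1).
#' @param seed Optional seed.
#' @return A list with `matrix` (the altered [contact_matrix]) and
#'   `truth` (tibble of all TADs with an `altered` flag).
#' @export
alter_single_tads <- function(M, tads, prop_tads = 0.5, prop_alter = 1,
                              seed = NULL) {
  stopifnot(inherits(M, "contact_matrix"), inherits(tads, "boundary_set"))
  if (prop_tads <= 0 || prop_tads > 1 || prop_alter < 0 || prop_alter > 1) {
    stop("`prop_tads` must be in (0, 1] and `prop_alter` in [0, 1]")
  }
  tt <- tads_from_boundaries(tads, M$n_bins)
  run <- function() {
    sel <- sort(sample.int(nrow(tt), ceiling(prop_tads * nrow(tt))))
    m <- M$counts
    n <- M$n_bins
    for (r in sel) {
      s <- tt$start_bin[r] + 1L   # 1-based
      e <- tt$end_bin[r] + 1L
      sz <- e - s + 1L
      ij <- which(upper.tri(matrix(0, sz, sz), diag = TRUE), arr.ind = TRUE)
      n_entries <- nrow(ij)
      pick <- sample.int(n_entries, ceiling(prop_alter * n_entries))
      if (!length(pick)) next
      ii <- ij[pick, 1L] + s - 1L
      jj <- ij[pick, 2L] + s - 1L
      d <- jj - ii
      for (dd in unique(d)) {
        at <- which(d == dd)
        src <- sample.int(n - dd, length(at), replace = TRUE)
        vals <- M$counts[cbind(src, src + dd)]
        m[cbind(ii[at], jj[at])] <- vals
        m[cbind(jj[at], ii[at])] <- vals
      }
    }
    list(m = m, sel = sel)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tt$altered <- seq_len(nrow(tt)) %in% out$sel
  alt <- M
  alt$counts <- out$m
  list(matrix = alt, truth = tt)
}

#' Split large TADs into sub-TADs with randomized inter-sub contacts
#'
#' Emulates hierarchical-TAD differences: among the TADs larger than
#' `size_thresh` bins, a fraction `prop_tads` is selected; each selected
#' TAD is split at a uniformly drawn point leaving both sub-TADs larger
#' than `min_sub` bins, and every contact between the two sub-TADs is
#' replaced by a count sampled uniformly from the whole off-diagonal
#' upper triangle of the map.  Because most entries of a contact map are
#' distal, low-count pairs, the substituted rectangle drops toward the
#' background contact level — emulating the loss of cross-sub-TAD
#' enrichment when one domain genuinely splits into two.  Intra-sub-TAD
#' contacts are untouched, which is what makes this condition hard:
#' short-distance strata stay nearly identical between the two maps.
#'
#' @param M A [contact_matrix].
#' @param tads A [boundary_set] with the TAD partition of `M`.
#' @param prop_tads Fraction of eligible TADs to split (default 0.5).
#' @param size_thresh Minimum TAD size (exclusive) for eligibility, in
#'   bins (default 10).
#' @param min_sub Minimum sub-TAD size (exclusive) after the split
#'   (default 5).
#' @param seed Optional seed.
#' @return A list with `matrix`, `truth` (all TADs with `altered` flag
#'   and `split_bin`, the last bin of the first sub-TAD, `NA` when not
#'   split) and `boundaries2` (the second sample's boundary set: the
#'   original boundaries plus the split points).
#' @export
alter_hierarchical_tads <- function(M, tads, prop_tads = 0.5,
                                    size_thresh = 10, min_sub = 5,
                                    seed = NULL) {
  stopifnot(inherits(M, "contact_matrix"), inherits(tads, "boundary_set"))
  tt <- tads_from_boundaries(tads, M$n_bins)
  tt$size <- tt$end_bin - tt$start_bin + 1L
  eligible <- which(tt$size > size_thresh)
  if (!length(eligible)) stop("no TAD larger than ", size_thresh, " bins")
  run <- function() {
    sel <- sort(sample(eligible, ceiling(prop_tads * length(eligible))))
    m <- M$counts
    n <- M$n_bins
    splits <- rep(NA_integer_, nrow(tt))
    for (r in sel) {
      sz <- tt$size[r]
      # first sub-TAD length c: both parts must exceed `min_sub` bins
      lo <- as.integer(min_sub) + 1L
      hi <- as.integer(sz) - as.integer(min_sub) - 1L
      if (hi < lo) next
      cfirst <- if (hi == lo) lo else sample(lo:hi, 1L)
      s <- tt$start_bin[r] + 1L
      split_last <- s + cfirst - 1L          # 1-based last bin of sub 1
      splits[r] <- tt$start_bin[r] + cfirst - 1L  # 0-based
      i_rng <- s:split_last
      j_rng <- (split_last + 1L):(tt$end_bin[r] + 1L)
      ij <- expand.grid(i = i_rng, j = j_rng)
      # source pool: every strict upper-triangle position of the map,
      # uniformly (row drawn with weight = number of columns above it)
      si <- sample.int(n - 1L, nrow(ij), replace = TRUE,
                       prob = (n - 1L):1L)
      sj <- si + 1L + floor(stats::runif(nrow(ij)) * (n - si))
      vals <- M$counts[cbind(si, sj)]
      m[cbind(ij$i, ij$j)] <- vals
      m[cbind(ij$j, ij$i)] <- vals
    }
    list(m = m, sel = sel, splits = splits)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tt$altered <- seq_len(nrow(tt)) %in% out$sel & !is.na(out$splits)
  tt$split_bin <- out$splits
  tt$split_bin[!tt$altered] <- NA_integer_
  alt <- M
  alt$counts <- out$m
  b2 <- boundary_set(c(tads$bins, stats::na.omit(tt$split_bin)),
                     sample_id = paste0(tads$sample_id, "+splits"))
  list(matrix = alt, truth = tt[, c("start_bin", "end_bin", "size",
                                    "altered", "split_bin")],
       boundaries2 = b2)
}

#' Simulate a random-ligation noise matrix
#'
#' Random ligation events are emulated by drawing, `C` times (`C` being
#' the total contact count of `M`), a bin pair `(i, j)` with each end
#' sampled independently with probability proportional to the marginal
#' coverage of `M`, and incrementing that entry.  The noise matrix has
#' exactly the same total contact count as `M`.
#'
#' @param M A [contact_matrix] with a positive total count.
#' @param seed Optional seed.
#' @return A [contact_matrix] of pure noise.
#' @export
make_noise_matrix <- function(M, seed = NULL) {
  stopifnot(inherits(M, "contact_matrix"))
  C <- total_contacts(M)
  if (C <= 0) stop("matrix has no contacts")
  C <- as.integer(round(C))
  run <- function() {
    n <- M$n_bins
    marg <- rowSums(M$counts)
    a <- sample.int(n, C, replace = TRUE, prob = marg)
    b <- sample.int(n, C, replace = TRUE, prob = marg)
    i <- pmin(a, b)
    j <- pmax(a, b)
    tab <- tabulate(i + (j - 1L) * n, nbins = n * n)
    up <- matrix(tab, n, n)    # all mass on/above the diagonal
    full <- up + t(up)
    diag(full) <- diag(up)
    full
  }
  m <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- M
  out$counts <- m
  out
}

#' Mix a signal matrix with a noise matrix
#'
#' With `mode = "convex"` (the default) the result is the rounded convex
#' combination `round((1 - level) * S + level * N)`, which keeps the
#' total depth of the signal matrix.  With `mode = "add"` the noise is
#' layered on top instead: `S + round(level * N)`, so the noise
#' contributes `level` times the depth of `N` in additional contacts.
#' Both keep integer count semantics.
#'
#' @param S Signal [contact_matrix].
#' @param N Noise [contact_matrix] of the same shape.
#' @param level Noise level in `[0, 1)`: the weight of the noise matrix.
#' @param mode `"convex"` or `"add"`.
#' @return A [contact_matrix].
#' @export
mix_noise <- function(S, N, level, mode = c("convex", "add")) {
  mode <- match.arg(mode)
  check_pair(S, N)
  if (level < 0 || level >= 1) stop("`level` must be in [0, 1)")
  if (level == 0) return(S)
  out <- S
  out$counts <- if (mode == "convex") {
    round((1 - level) * S$counts + level * N$counts)
  } else {
    S$counts + round(level * N$counts)
  }
  out
}

#' Binomial down-sampling of a count matrix
#'
#' Each upper-triangle entry is independently replaced by a
#' `Binomial(M[i, j], p)` draw, emulating a lower sequencing coverage of
#' relative depth `p`; zero entries stay zero.
#'
#' @param M A [contact_matrix] with integer counts.
#' @param p Relative coverage in `(0, 1]`.
#' @param seed Optional seed.
#' @return A down-sampled [contact_matrix].
#' @export
downsample <- function(M, p, seed = NULL) {
  stopifnot(inherits(M, "contact_matrix"))
  if (p <= 0 || p > 1) stop("`p` must be in (0, 1]")
  if (any(M$counts != round(M$counts))) {
    stop("down-sampling needs raw integer counts")
  }
  if (p == 1) return(M)
  run <- function() {
    n <- M$n_bins
    up <- which(upper.tri(M$counts, diag = TRUE) & M$counts > 0)
    m <- matrix(0, n, n)
    m[up] <- stats::rbinom(length(up), size = as.integer(M$counts[up]),
                           prob = p)
    pmax(m, t(m))
  }
  m <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- M
  out$counts <- m
  out
}

#' Score region-level calls against simulation ground truth
#'
#' The truth is projected onto the caller's candidate regions with the
#' same rule the caller itself uses: a candidate region is truly
#' differential when an altered TAD covers strictly more than a third of
#' it.  The false detection rate is `(FP + FN) / N` over the `N`
#' candidate regions, i.e. one minus the accuracy.
#'
#' @param calls The `calls` tibble of a [run_diffgr()] result (or the
#'   result object).
#' @param truth Truth tibble from [alter_single_tads()] or
#'   [alter_hierarchical_tads()] (TAD intervals with an `altered` flag),
#'   or `NULL` when no region is truly altered (e.g. pure
#'   coverage/replicate comparisons).
#' @return A one-row tibble: `n_regions`, `tp`, `fp`, `tn`, `fn`,
#'   `false_detection_rate`, `accuracy`, `sensitivity`, `specificity`.
#' @export
evaluate_calls <- function(calls, truth = NULL) {
  if (inherits(calls, "diffgr_result")) calls <- calls$calls
  n <- nrow(calls)
  if (!n) stop("no candidate regions to evaluate")
  if (is.null(truth) || !any(truth$altered)) {
    true_diff <- rep(FALSE, n)
  } else {
    alt <- truth[truth$altered, , drop = FALSE]
    true_diff <- vapply(seq_len(n), function(r) {
      reg_len <- calls$end_bin[r] - calls$start_bin[r] + 1L
      ov <- pmin(calls$end_bin[r], alt$end_bin) -
        pmax(calls$start_bin[r], alt$start_bin) + 1L
      any(3 * ov > reg_len)
    }, logical(1))
  }
  called <- calls$differential
  tp <- sum(called & true_diff)
  fp <- sum(called & !true_diff)
  tn <- sum(!called & !true_diff)
  fn <- sum(!called & true_diff)
  tibble::tibble(
    n_regions = n, tp = tp, fp = fp, tn = tn, fn = fn,
    false_detection_rate = (fp + fn) / n,
    accuracy = 1 - (fp + fn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}
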