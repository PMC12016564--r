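#' Merge TAD boundaries from two samples
#'
#' Boundaries within `merge_dist` bins of each other across the two
#' samples are treated as one common boundary placed at the (floored)
#' middle bin; the remainder are kept as boundaries unique to one sample.
#' Pairing is greedy on the globally nearest cross-sample partner, each
#' boundary used at most once, distance ties broken leftward; the rule is
#' deterministic and symmetric in the two samples.  The chromosome end bin
#' is always a common boundary.
#'
#' @param b1,b2 [boundary_set] objects for the two samples.
#' @param n_bins Number of bins of the chromosome.
#' @param merge_dist Maximum bin distance at which two boundaries are
#'   merged (default 2).
#' @return A list of class `merged_boundaries` with sorted integer vectors
#'   `common`, `unique1`, `unique2`.
#' @export
merge_boundaries <- function(b1, b2, n_bins, merge_dist = 2) {
  stopifnot(inherits(b1, "boundary_set"), inherits(b2, "boundary_set"))
  end_bin <- n_bins - 1L
  x <- b1$bins[b1$bins < end_bin]
  y <- b2$bins[b2$bins < end_bin]
  if (any(b1$bins > end_bin) || any(b2$bins > end_bin)) {
    stop("boundary bin index beyond chromosome end")
  }
  # all cross-sample pairs within range, closest first; on equal distance
  # the leftmost pair wins, which keeps the rule symmetric in the samples
  pairs <- expand.grid(i = seq_along(x), j = seq_along(y))
  pairs$d <- abs(x[pairs$i] - y[pairs$j])
  pairs <- pairs[pairs$d <= merge_dist, , drop = FALSE]
  pairs <- pairs[order(pairs$d, pmin(x[pairs$i], y[pairs$j]),
                       pmax(x[pairs$i], y[pairs$j])), , drop = FALSE]
  used_x <- rep(FALSE, length(x))
  used_y <- rep(FALSE, length(y))
  common <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (used_x[i] || used_y[j]) next
    used_x[i] <- TRUE
    used_y[j] <- TRUE
    common <- c(common, (x[i] + y[j]) %/% 2L)
  }
  unique1 <- x[!used_x]
  unique2 <- y[!used_y]
  common <- sort(unique(c(common, end_bin)))
  # a merged midpoint can collide with a unique boundary; common wins
  unique1 <- sort(setdiff(unique1, common))
  unique2 <- sort(setdiff(unique2, common))
  structure(list(common = as.integer(common),
                 unique1 = as.integer(unique1),
                 unique2 = as.integer(unique2)),
            class = "merged_boundaries")
}

#' Partition a chromosome into candidate regions
#'
#' Consecutive common boundaries define non-overlapping candidate regions
#' covering every bin of the chromosome.  Each region is classified by the
#' unique boundaries strictly inside it: `single` (none), `hierarchical`
#' (all from one sample), or `complex` (both samples contribute).
#'
#' @param mb A `merged_boundaries` object from [merge_boundaries()].
#' @param n_bins Number of bins of the chromosome.
#' @return A tibble with one row per region: `region_id`, `start_bin`,
#'   `end_bin` (inclusive bin interval), `kind`, `n_unique`, and the
#'   list-columns `unique_bins`, `unique_sample` describing the internal
#'   unique boundaries.
#' @export
build_candidate_regions <- function(mb, n_bins) {
  stopifnot(inherits(mb, "merged_boundaries"))
  ends <- mb$common
  starts <- c(0L, utils::head(ends, -1L) + 1L)
  regions <- purrr::map2(starts, ends, function(s, e) {
    in1 <- mb$unique1[mb$unique1 > s & mb$unique1 < e]
    in2 <- mb$unique2[mb$unique2 > s & mb$unique2 < e]
    # uniques at the region start bin - 1 or at the end bin are flanks of
    # neighbouring regions, not internal structure; strict interior only
    k1 <- length(in1); k2 <- length(in2)
    kind <- if (k1 + k2 == 0) "single"
      else if (k1 == 0 || k2 == 0) "hierarchical"
      else "complex"
    ub <- sort(c(in1, in2))
    us <- c(rep(1L, k1), rep(2L, k2))[order(c(in1, in2))]
    tibble::tibble(start_bin = s, end_bin = e, kind = kind,
                   n_unique = k1 + k2,
                   unique_bins = list(ub), unique_sample = list(us))
  })
  out <- dplyr::bind_rows(regions)
  dplyr::mutate(out, region_id = dplyr::row_number(),
                .before = "start_bin")
}

#' Enumerate potential differential (sub-)TADs of a candidate region
#'
#' A region flanked by two common boundaries and containing `k` internal
#' unique boundaries has `k + 2` ordered boundary positions, and every
#' pair of them delimits one potential (sub-)TAD: `choose(k + 2, 2)`
#' intervals in total.  An internal boundary at bin `b` splits intervals
#' as `[.., b]` and `[b + 1, ..]`, consistent with the last-bin-of-TAD
#' convention.  Intervals shorter than `min_size` bins are dropped:
#' correlating fewer than 3 strata is degenerate.
#'
#' @param region One row of the tibble from [build_candidate_regions()]
#'   (or any list with `start_bin`, `end_bin`, `unique_bins`).
#' @param min_size Minimum interval length in bins (default 3).
#' @return A tibble with columns `start_bin`, `end_bin`, `length_bins`.
#' @export
enumerate_potential_tads <- function(region, min_size = 3) {
  s <- region$start_bin
  e <- region$end_bin
  ub <- region$unique_bins
  if (is.list(ub)) ub <- ub[[1]]
  # ordered boundary positions: left flank, internal uniques, right flank
  pos <- c(s - 1L, sort(ub), e)  # last-bin indices; s - 1 opens the region
  pairs <- utils::combn(seq_along(pos), 2L)
  starts <- pos[pairs[1L, ]] + 1L
  ends <- pos[pairs[2L, ]]
  out <- tibble::tibble(start_bin = as.integer(starts),
                        end_bin = as.integer(ends),
                        length_bins = as.integer(ends - starts + 1L))
  dplyr::arrange(dplyr::filter(out, .data$length_bins >= min_size),
                 .data$start_bin, .data$end_bin)
}
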