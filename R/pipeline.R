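#' Configuration for a differential-region run
#'
#' Collects every tunable of the three-step procedure with the method's
#' defaults.
#'
#' @param smooth Apply the 2D mean filter before balancing (default
#'   `TRUE`).
#' @param smooth_h Mean-filter radius in bins; `NULL` picks the
#'   resolution-dependent default of [default_smooth_h()].
#' @param kr Apply Knight-Ruiz balancing (default `TRUE`).
#' @param kr_tol Balancing tolerance.
#' @param max_dist Genomic distance cap for SCC strata in bp (default
#'   10 Mb).
#' @param nperm Permutations per unique TAD size (default 2000).
#' @param alpha Significance level (default 0.05).
#' @param theta Similarity threshold in (0, 1), or `"auto"` to derive it
#'   per TAD size from a pseudo-replicate split of the pooled counts, or
#'   `NA` to disable the filter.
#' @param min_tad_size Smallest testable (sub-)TAD in bins (default 3).
#' @param merge_dist Boundary merge distance in bins (default 2).
#' @param speedup Fit null quantile curves over a subset of TAD sizes
#'   instead of permuting every size (default `FALSE`).
#' @param n_knots Number of exactly permuted sizes in speed-up mode.
#' @param add_one Use the `(r + 1) / (N + 1)` p-value convention.
#' @param seed Integer master seed; per-size substreams are derived from
#'   it so cached nulls are reproducible.
#' @return A list of class `diffgr_config`.
#' @export
diffgr_config <- function(smooth = TRUE, smooth_h = NULL, kr = TRUE,
                          kr_tol = 1e-6, max_dist = 1e7, nperm = 2000,
                          alpha = 0.05, theta = 0.85, min_tad_size = 3,
                          merge_dist = 2, speedup = FALSE, n_knots = 8,
                          add_one = FALSE, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  if (is.numeric(theta) && !is.na(theta) && (theta <= 0 || theta >= 1)) {
    stop("`theta` must be in (0, 1), \"auto\", or NA")
  }
  structure(list(smooth = smooth, smooth_h = smooth_h, kr = kr,
                 kr_tol = kr_tol, max_dist = max_dist, nperm = nperm,
                 alpha = alpha, theta = theta,
                 min_tad_size = min_tad_size, merge_dist = merge_dist,
                 speedup = speedup, n_knots = n_knots, add_one = add_one,
                 seed = as.integer(seed)),
            class = "diffgr_config")
}

# deterministic per-task substream seed, kept inside the 32-bit range
derive_seed <- function(seed, key) {
  as.integer(((as.numeric(seed) %% 2147483647) * 69069 + 97003 * key) %%
               2147483562) + 1L
}

preprocess_matrix <- function(M, cfg) {
  if (cfg$smooth) {
    h <- if (is.null(cfg$smooth_h)) default_smooth_h(M$resolution)
         else cfg$smooth_h
    M <- mean_filter(M, h)
  }
  if (cfg$kr) M <- kr_normalize(M, tol = cfg$kr_tol)
  M
}

#' Detect differentially interacting genomic regions between two Hi-C maps
#'
#' Runs the full three-step procedure on one chromosome: (1) both contact
#' maps are smoothed and Knight-Ruiz balanced, and the two samples' TAD
#' boundaries are merged into common and unique sets that partition the
#' chromosome into single-, hierarchical- and complex-type candidate
#' regions; (2) every potential (sub-)TAD delimited by two of a region's
#' boundaries is scored with the local stratum-adjusted correlation
#' coefficient; (3) each observed SCC is referred to a permutation null of
#' random pseudo-TADs of the same size, p-values are similarity-filtered
#' and Benjamini-Hochberg adjusted, and a region is called differential
#' when at least one of its TADs is significant and the largest
#' significant TAD spans more than a third of the region.
#'
#' @param M1,M2 [contact_matrix] objects on the same chromosome, bins and
#'   resolution.
#' @param b1,b2 [boundary_set] objects with each sample's TAD boundaries.
#' @param cfg A [diffgr_config].
#' @return An object of class `diffgr_result`: list with tibbles `calls`
#'   (one row per candidate region) and `tests` (one row per tested
#'   potential TAD), the `merged` boundary classification, and `config`.
#' @examples
#' sim <- generate_base_matrix(base_matrix_config(n_bins = 120, n_tads = 6,
#'   total_contacts = 2e5, seed = 7))
#' res <- run_diffgr(sim$matrix, sim$matrix, sim$boundaries,
#'                   sim$boundaries,
#'                   diffgr_config(nperm = 200, seed = 7))
#' sum(res$calls$differential)  # identical maps: 0
#' @export
run_diffgr <- function(M1, M2, b1, b2, cfg = diffgr_config()) {
  check_pair(M1, M2)
  stopifnot(inherits(cfg, "diffgr_config"))
  n <- M1$n_bins

  mb <- merge_boundaries(b1, b2, n, merge_dist = cfg$merge_dist)
  regions <- build_candidate_regions(mb, n)
  tests <- dplyr::bind_rows(purrr::map(seq_len(nrow(regions)), function(r) {
    td <- enumerate_potential_tads(regions[r, ], min_size = cfg$min_tad_size)
    if (nrow(td)) td$region_id <- regions$region_id[r]
    td
  }))

  auto_theta_mode <- identical(cfg$theta, "auto")
  P1 <- preprocess_matrix(M1, cfg)
  P2 <- preprocess_matrix(M2, cfg)
  if (auto_theta_mode) {
    reps <- pseudo_replicates(pool_matrices(M1, M2),
                              seed = derive_seed(cfg$seed, 777))
    R1 <- preprocess_matrix(reps[[1]], cfg)
    R2 <- preprocess_matrix(reps[[2]], cfg)
  }

  if (nrow(tests)) {
    obs <- purrr::map2(tests$start_bin, tests$end_bin,
                       ~ scc(P1, P2, .x, .y, max_dist = cfg$max_dist))
    obs <- dplyr::bind_rows(obs)
    tests$rho <- obs$rho
    tests$defined <- obs$defined
    pv <- compute_pvalues(tests, P1, P2, cfg)
    tests <- pv$tests
    if (auto_theta_mode) {
      tests$theta <- auto_theta_by_size(tests, pv$nulls, P1, P2, R1, R2, cfg)
    } else {
      tests$theta <- if (is.na(cfg$theta)) NA_real_ else cfg$theta
    }
    # the similarity filter acts on the raw permutation p-values, element
    # by element (theta can vary with TAD size in auto mode)
    tests$p_adj <- ifelse(!is.na(tests$p) & !is.na(tests$rho) &
                            !is.na(tests$theta) &
                            tests$p < cfg$alpha & tests$rho > tests$theta,
                          0.5, tests$p)
    tests$q <- bh_adjust(tests$p_adj)
    tests$significant <- !is.na(tests$q) & tests$q < cfg$alpha
  } else {
    tests <- tibble::tibble(start_bin = integer(0), end_bin = integer(0),
                            length_bins = integer(0), region_id = integer(0),
                            rho = numeric(0), defined = logical(0),
                            p = numeric(0), theta = numeric(0),
                            p_adj = numeric(0), q = numeric(0),
                            significant = logical(0))
  }

  calls <- region_calls(regions, tests, M1)
  structure(list(calls = calls, tests = tests, merged = mb, config = cfg,
                 chrom = M1$chrom, resolution = M1$resolution,
                 n_bins = n),
            class = "diffgr_result")
}

# p-values per potential TAD, permuting once per unique size (cached); in
# speed-up mode only `n_knots` sizes are permuted exactly and the rest are
# read off interpolated null quantile curves.
compute_pvalues <- function(tests, P1, P2, cfg) {
  tests$p <- NA_real_
  sizes <- sort(unique(tests$length_bins[tests$defined]))
  if (!length(sizes)) return(list(tests = tests, nulls = list()))
  exact_sizes <- sizes
  surface <- NULL
  if (cfg$speedup && length(sizes) > cfg$n_knots) {
    exact_sizes <- sizes[unique(round(seq(1, length(sizes),
                                          length.out = cfg$n_knots)))]
  }
  nulls <- lapply(exact_sizes, function(L) {
    null_scc_distribution(P1, P2, L, N = cfg$nperm,
                          max_dist = cfg$max_dist,
                          seed = derive_seed(cfg$seed, L))
  })
  names(nulls) <- as.character(exact_sizes)
  if (cfg$speedup && length(sizes) > cfg$n_knots) {
    surface <- fit_null_cdf_surface(exact_sizes, nulls)
  }
  for (idx in seq_len(nrow(tests))) {
    if (!tests$defined[idx]) next
    L <- tests$length_bins[idx]
    key <- as.character(L)
    if (!is.null(nulls[[key]])) {
      tests$p[idx] <- permutation_pvalue(tests$rho[idx], nulls[[key]],
                                         add_one = cfg$add_one)
    } else {
      p <- surface(tests$rho[idx], L)
      if (is.na(p)) {  # outside fitted range: exact fallback
        nulls[[key]] <- null_scc_distribution(
          P1, P2, L, N = cfg$nperm, max_dist = cfg$max_dist,
          seed = derive_seed(cfg$seed, L))
        p <- permutation_pvalue(tests$rho[idx], nulls[[key]],
                                add_one = cfg$add_one)
      }
      tests$p[idx] <- p
    }
  }
  list(tests = tests, nulls = nulls)
}

# per-size automatic theta: midpoint of the alpha-quantiles of the
# non-replicate null (P1 vs P2, reusing the cached test nulls) and the
# pseudo-replicate null (R1 vs R2)
auto_theta_by_size <- function(tests, nulls, P1, P2, R1, R2, cfg) {
  theta <- rep(NA_real_, nrow(tests))
  for (L in unique(tests$length_bins[tests$defined])) {
    key <- as.character(L)
    nd_nr <- nulls[[key]]
    if (is.null(nd_nr)) {
      nd_nr <- null_scc_distribution(
        P1, P2, L, N = cfg$nperm, max_dist = cfg$max_dist,
        seed = derive_seed(cfg$seed, L))
    }
    nd_br <- null_scc_distribution(
      R1, R2, L, N = cfg$nperm, max_dist = cfg$max_dist,
      seed = derive_seed(cfg$seed, 100000 + L))
    q_nr <- stats::quantile(nd_nr$values, cfg$alpha, names = FALSE)
    q_br <- stats::quantile(nd_br$values, cfg$alpha, names = FALSE)
    theta[tests$length_bins == L] <- (q_nr + q_br) / 2
  }
  theta
}

region_calls <- function(regions, tests, M) {
  res <- M$resolution
  off <- M$offset
  rows <- purrr::map(seq_len(nrow(regions)), function(r) {
    rg <- regions[r, ]
    tt <- tests[!is.na(tests$region_id) & tests$region_id == rg$region_id, ,
                drop = FALSE]
    reg_len <- rg$end_bin - rg$start_bin + 1L
    sig <- tt[tt$significant %in% TRUE, , drop = FALSE]
    notice <- NULL
    differential <- FALSE
    if (nrow(sig)) {
      best <- sig[which.max(sig$length_bins), ]
      if (3 * best$length_bins > reg_len) {
        differential <- TRUE
        notice <- best
      }
    }
    whole <- tt[tt$start_bin == rg$start_bin & tt$end_bin == rg$end_bin, ,
                drop = FALSE]
    tibble::tibble(
      region_id = rg$region_id,
      chrom = M$chrom,
      start_bin = rg$start_bin, end_bin = rg$end_bin,
      start_bp = off + rg$start_bin * res,
      end_bp = off + (rg$end_bin + 1) * res,
      kind = rg$kind,
      n_tests = nrow(tt),
      n_significant = nrow(sig),
      scc = if (nrow(whole)) whole$rho[1] else NA_real_,
      min_p = if (nrow(tt) && any(!is.na(tt$p))) min(tt$p, na.rm = TRUE)
              else NA_real_,
      min_q = if (nrow(tt) && any(!is.na(tt$q))) min(tt$q, na.rm = TRUE)
              else NA_real_,
      differential = differential,
      untestable = nrow(tt) == 0 || !any(tt$defined),
      noticeable_start_bin = if (differential) notice$start_bin
                             else NA_integer_,
      noticeable_end_bin = if (differential) notice$end_bin
                           else NA_integer_
    )
  })
  dplyr::bind_rows(rows)
}

#' Summarize region-level calls by candidate type
#'
#' @param calls The `calls` tibble of a [run_diffgr()] result (or the
#'   result object itself).
#' @return A tibble with one row per candidate kind plus an `all` row:
#'   region counts and proportions, and differential counts and
#'   proportions within each kind.
#' @export
summarize_calls <- function(calls) {
  if (inherits(calls, "diffgr_result")) calls <- calls$calls
  if (!nrow(calls)) {
    return(tibble::tibble(kind = "all", n_regions = 0L, prop_regions = 0,
                          n_differential = 0L, prop_differential = 0))
  }
  by_kind <- calls |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(n_regions = dplyr::n(),
                     n_differential = sum(.data$differential),
                     .groups = "drop") |>
    dplyr::mutate(prop_regions = .data$n_regions / sum(.data$n_regions),
                  prop_differential = ifelse(
                    .data$n_regions > 0,
                    .data$n_differential / .data$n_regions, 0))
  all_row <- tibble::tibble(
    kind = "all", n_regions = nrow(calls),
    n_differential = sum(calls$differential),
    prop_regions = 1,
    prop_differential = sum(calls$differential) / nrow(calls))
  dplyr::bind_rows(by_kind, all_row)[
    , c("kind", "n_regions", "prop_regions", "n_differential",
        "prop_differential")]
}

#' Pool two raw contact matrices
#'
#' @param M1,M2 [contact_matrix] objects on the same bins.
#' @return A [contact_matrix] with entrywise summed counts.
#' @export
pool_matrices <- function(M1, M2) {
  check_pair(M1, M2)
  out <- M1
  out$counts <- M1$counts + M2$counts
  out
}

#' Split a pooled matrix into two pseudo-replicates
#'
#' Each pooled contact is assigned to replicate A with probability 1/2
#' (binomial thinning of every upper-triangle entry); replicate B receives
#' the remainder, so the two halves sum exactly to the input.
#'
#' @param M A [contact_matrix] with integer counts.
#' @param seed Optional seed for a reproducible split.
#' @return List of two [contact_matrix] halves.
#' @export
pseudo_replicates <- function(M, seed = NULL) {
  stopifnot(inherits(M, "contact_matrix"))
  if (any(M$counts != round(M$counts))) {
    stop("pseudo-replicate splitting needs integer counts")
  }
  split1 <- function() {
    n <- M$n_bins
    up <- upper.tri(M$counts, diag = TRUE)
    a <- matrix(0, n, n)
    a[up] <- stats::rbinom(sum(up), size = as.integer(M$counts[up]),
                           prob = 0.5)
    a <- pmax(a, t(a))
    a
  }
  A <- if (is.null(seed)) split1() else withr::with_seed(seed, split1())
  MA <- M; MA$counts <- A
  MB <- M; MB$counts <- M$counts - A
  list(MA, MB)
}

#' @export
print.diffgr_result <- function(x, ...) {
  cat(sprintf(
    "<diffgr_result> %s: %d candidate regions, %d differential (%s)\n",
    x$chrom, nrow(x$calls), sum(x$calls$differential),
    paste0(round(100 * mean(x$calls$differential), 2), "%")))
  invisible(x)
}
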