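test_that("the base generator is reproducible and tiles its TADs", {
  a <- toy_simulation(n_bins = 200, n_tads = 8, total = 2e5, seed = 3)
  b <- toy_simulation(n_bins = 200, n_tads = 8, total = 2e5, seed = 3)
  expect_identical(a$matrix$counts, b$matrix$counts)
  c <- toy_simulation(n_bins = 200, n_tads = 8, total = 2e5, seed = 4)
  expect_false(identical(a$matrix$counts, c$matrix$counts))

  expect_equal(nrow(a$tads), 8)
  expect_identical(a$tads$start_bin[1], 0L)
  expect_identical(a$tads$end_bin[8], 199L)
  expect_identical(a$tads$start_bin[-1], a$tads$end_bin[-8] + 1L)
  expect_true(all(a$tads$size >= 6))
  expect_identical(a$boundaries$bins, a$tads$end_bin)
  expect_true(isSymmetric(a$matrix$counts))
})

test_that("the generator hits its target depth and intra-TAD enrichment", {
  sim <- toy_simulation(n_bins = 480, n_tads = 20, total = 6e5, seed = 5)
  tot <- total_contacts(sim$matrix)
  # Poisson totals concentrate tightly around the configured expectation
  expect_lt(abs(tot - 6e5) / 6e5, 0.05)

  # distance-matched mean contrast between same-TAD and cross-TAD pairs
  tad_id <- rep(seq_len(nrow(sim$tads)), sim$tads$size)
  ratios <- sapply(1:5, function(d) {
    i <- seq_len(480 - d)
    v <- sim$matrix$counts[cbind(i, i + d)]
    same <- tad_id[i] == tad_id[i + d]
    mean(v[same]) / mean(v[!same])
  })
  expect_gt(mean(ratios), 2)
  expect_lt(mean(ratios), 4)
})

test_that("single-TAD alteration touches only the selected TADs", {
  sim <- toy_simulation(n_bins = 240, n_tads = 10, total = 3e5, seed = 6)
  alt <- alter_single_tads(sim$matrix, sim$boundaries, 0.4, 1, seed = 8)
  expect_equal(sum(alt$truth$altered), ceiling(0.4 * 10))

  tad_id <- rep(seq_len(nrow(sim$tads)), sim$tads$size)
  altered_bins <- which(tad_id %in% which(alt$truth$altered))
  outside <- matrix(TRUE, 240, 240)
  outside[altered_bins, altered_bins] <- FALSE
  expect_identical(alt$matrix$counts[outside], sim$matrix$counts[outside])

  # substituted entries take values that exist on the same diagonal of
  # the original map
  changed <- which(alt$matrix$counts != sim$matrix$counts, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  for (r in sample(nrow(changed), 25)) {
    i <- changed[r, 1]; j <- changed[r, 2]
    d <- abs(i - j)
    k <- seq_len(240 - d)
    diag_vals <- sim$matrix$counts[cbind(k, k + d)]
    expect_true(alt$matrix$counts[i, j] %in% diag_vals)
  }
})

test_that("a zero substitution fraction leaves the map unchanged", {
  sim <- toy_simulation(n_bins = 120, n_tads = 5, total = 8e4, seed = 7)
  alt <- alter_single_tads(sim$matrix, sim$boundaries, 0.5, 0, seed = 9)
  expect_identical(alt$matrix$counts, sim$matrix$counts)
  expect_equal(sum(alt$truth$altered), 3)
})

test_that("hierarchical alteration splits TADs and keeps sub-TADs intact", {
  sim <- toy_simulation(n_bins = 360, n_tads = 12, total = 4e5, seed = 8)
  alt <- alter_hierarchical_tads(sim$matrix, sim$boundaries, 0.5, seed = 10)
  tr <- alt$truth[alt$truth$altered, ]
  expect_gt(nrow(tr), 0)
  # both sub-TADs strictly exceed the minimum size
  first <- tr$split_bin - tr$start_bin + 1L
  second <- tr$end_bin - tr$split_bin
  expect_true(all(first > 5 & second > 5))
  # the second sample's boundaries are the originals plus the splits
  expect_identical(alt$boundaries2$bins,
                   sort(unique(c(sim$boundaries$bins, tr$split_bin))))
  # intra-sub-TAD contacts are untouched; only the rectangle between the
  # two sub-TADs is replaced
  for (r in seq_len(nrow(tr))) {
    s <- tr$start_bin[r] + 1L
    m <- tr$split_bin[r] + 1L
    e <- tr$end_bin[r] + 1L
    expect_identical(alt$matrix$counts[s:m, s:m],
                     sim$matrix$counts[s:m, s:m])
    expect_identical(alt$matrix$counts[(m + 1):e, (m + 1):e],
                     sim$matrix$counts[(m + 1):e, (m + 1):e])
    expect_false(identical(alt$matrix$counts[s:m, (m + 1):e],
                           sim$matrix$counts[s:m, (m + 1):e]))
  }
})

test_that("a TAD of twice the minimum splits exactly in the middle", {
  sim <- toy_simulation(n_bins = 24, n_tads = 2, total = 3e4, seed = 9)
  # force both TADs to 12 bins
  b <- boundary_set(c(11L, 23L), sample_id = "truth")
  m <- sim$matrix
  alt <- alter_hierarchical_tads(m, b, prop_tads = 1, seed = 11)
  tr <- alt$truth[alt$truth$altered, ]
  # with min_sub = 5 a 12-bin TAD admits only the 6 + 6 split
  expect_identical(tr$split_bin - tr$start_bin + 1L,
                   rep(6L, nrow(tr)))
})

test_that("the noise matrix conserves depth and respects coverage", {
  sim <- toy_simulation(n_bins = 150, n_tads = 6, total = 1e5, seed = 10)
  N <- make_noise_matrix(sim$matrix, seed = 12)
  expect_equal(total_contacts(N), total_contacts(sim$matrix))
  expect_true(isSymmetric(N$counts))
  # a bin with zero marginal coverage receives no noise contacts
  z <- sim$matrix
  z$counts[3, ] <- 0
  z$counts[, 3] <- 0
  N2 <- make_noise_matrix(z, seed = 13)
  expect_true(all(N2$counts[3, ] == 0))
})

test_that("noise mixing is a rounded convex combination", {
  sim <- toy_simulation(n_bins = 100, n_tads = 4, total = 6e4, seed = 11)
  N <- make_noise_matrix(sim$matrix, seed = 14)
  expect_identical(mix_noise(sim$matrix, N, 0)$counts, sim$matrix$counts)
  mixed <- mix_noise(sim$matrix, N, 0.3)
  expect_equal(mixed$counts,
               round(0.7 * sim$matrix$counts + 0.3 * N$counts))
  # mixing a matrix with itself is the identity at any level
  expect_equal(mix_noise(sim$matrix, sim$matrix, 0.5)$counts,
               sim$matrix$counts)
  expect_error(mix_noise(sim$matrix, N, 1))
  # additive mode layers scaled noise on top of the signal
  added <- mix_noise(sim$matrix, N, 0.2, mode = "add")
  expect_equal(added$counts, sim$matrix$counts + round(0.2 * N$counts))
})

test_that("down-sampling thins counts binomially", {
  sim <- toy_simulation(n_bins = 200, n_tads = 8, total = 4e5, seed = 12)
  expect_identical(downsample(sim$matrix, 1)$counts, sim$matrix$counts)
  ds <- downsample(sim$matrix, 0.4, seed = 15)
  expect_true(all(ds$counts <= sim$matrix$counts))
  expect_true(all(ds$counts[sim$matrix$counts == 0] == 0))
  expect_true(isSymmetric(ds$counts))
  tot <- total_contacts(sim$matrix)
  got <- total_contacts(ds)
  se <- sqrt(tot * 0.4 * 0.6)
  expect_lt(abs(got - 0.4 * tot), 4 * se)
  expect_error(downsample(sim$matrix, 0))
})

test_that("call scoring reproduces the confusion-matrix formulas", {
  calls <- tibble::tibble(
    start_bin = c(0L, 10L, 20L, 30L),
    end_bin = c(9L, 19L, 29L, 39L),
    differential = c(TRUE, FALSE, TRUE, FALSE))
  truth <- tibble::tibble(
    start_bin = c(0L, 20L), end_bin = c(9L, 24L),
    altered = c(TRUE, TRUE))
  # region 1 fully altered (TP); region 3 overlaps 5 of 10 bins, and
  # 3 * 5 > 10, so it is truly differential too (TP); regions 2 and 4 TN
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$tp, 2)
  expect_equal(ev$fp, 0)
  expect_equal(ev$tn, 2)
  expect_equal(ev$fn, 0)
  expect_equal(ev$false_detection_rate, 0)
  expect_equal(ev$accuracy, 1)

  # with no truth every call is a false positive
  ev2 <- evaluate_calls(calls, NULL)
  expect_equal(ev2$fp, 2)
  expect_equal(ev2$false_detection_rate, 0.5)
  expect_true(is.na(ev2$sensitivity))
})
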