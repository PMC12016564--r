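bset <- function(bins, id = "s") boundary_set(as.integer(bins), sample_id = id)

test_that("boundary merging pairs nearby boundaries at the midpoint", {
  mb <- merge_boundaries(bset(c(9, 19)), bset(c(10, 19)), n_bins = 30)
  # 9 and 10 merge to bin 9; the chromosome end bin 29 is always common
  expect_identical(mb$common, c(9L, 19L, 29L))
  expect_identical(mb$unique1, integer(0))
  expect_identical(mb$unique2, integer(0))
})

test_that("unmatched boundaries stay unique to their sample", {
  mb <- merge_boundaries(bset(c(9, 19)), bset(19), n_bins = 30)
  expect_identical(mb$common, c(19L, 29L))
  expect_identical(mb$unique1, 9L)
  mb2 <- merge_boundaries(bset(c(5, 19)), bset(c(12, 19)), n_bins = 30)
  expect_identical(mb2$unique1, 5L)
  expect_identical(mb2$unique2, 12L)
})

test_that("boundary merging is symmetric in the two samples", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      n <- 60L
      a <- sort(sample.int(n - 1L, 8)) - 1L
      b <- sort(sample.int(n - 1L, 8)) - 1L
      m12 <- merge_boundaries(bset(a), bset(b), n)
      m21 <- merge_boundaries(bset(b), bset(a), n)
      expect_identical(m12$common, m21$common)
      expect_identical(m12$unique1, m21$unique2)
      expect_identical(m12$unique2, m21$unique1)
    }
  })
})

test_that("every boundary is accounted for exactly once", {
  withr::with_seed(9, {
    for (rep in 1:10) {
      n <- 80L
      a <- sort(sample.int(n - 1L, 10)) - 1L
      b <- sort(sample.int(n - 1L, 10)) - 1L
      mb <- merge_boundaries(bset(a), bset(b), n)
      # uniques come from their own sample and never sit on a common bin
      expect_true(all(mb$unique1 %in% a))
      expect_true(all(mb$unique2 %in% b))
      expect_length(intersect(mb$unique1, mb$common), 0)
      expect_length(intersect(mb$unique2, mb$common), 0)
      expect_true((n - 1L) %in% mb$common)
    }
  })
})

test_that("candidate regions tile the chromosome and are classified", {
  # two common boundaries split 30 bins into three single regions
  mb <- merge_boundaries(bset(c(9, 19)), bset(c(9, 19)), n_bins = 30)
  reg <- build_candidate_regions(mb, 30)
  expect_equal(nrow(reg), 3)
  expect_identical(reg$start_bin, c(0L, 10L, 20L))
  expect_identical(reg$end_bin, c(9L, 19L, 29L))
  expect_true(all(reg$kind == "single"))

  # one internal boundary from sample 1 makes the region hierarchical
  mb2 <- merge_boundaries(bset(c(9, 19)), bset(19), n_bins = 30)
  reg2 <- build_candidate_regions(mb2, 30)
  r <- reg2[reg2$start_bin == 0, ]
  expect_identical(r$kind, "hierarchical")
  expect_identical(r$unique_bins[[1]], 9L)

  # internal boundaries from both samples make it complex
  mb3 <- merge_boundaries(bset(c(5, 19)), bset(c(12, 19)), n_bins = 30)
  reg3 <- build_candidate_regions(mb3, 30)
  r3 <- reg3[reg3$start_bin == 0, ]
  expect_identical(r3$kind, "complex")
  expect_identical(r3$unique_bins[[1]], c(5L, 12L))
  expect_identical(r3$unique_sample[[1]], c(1L, 2L))
})

test_that("regions always cover all bins without gaps or overlap", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- 100L
      a <- sort(sample.int(n - 1L, 12)) - 1L
      b <- sort(sample.int(n - 1L, 12)) - 1L
      mb <- merge_boundaries(bset(a), bset(b), n)
      reg <- build_candidate_regions(mb, n)
      covered <- unlist(purrr::map2(reg$start_bin, reg$end_bin, seq))
      expect_identical(sort(covered), 0:(n - 1L))
      expect_identical(length(covered), as.integer(n))
    }
  })
})

test_that("potential TAD enumeration yields choose(k + 2, 2) intervals", {
  region <- list(start_bin = 0L, end_bin = 19L, unique_bins = list(9L))
  tads <- enumerate_potential_tads(region, min_size = 3)
  # k = 1 internal boundary: choose(3, 2) = 3 intervals, all length >= 3
  expect_equal(nrow(tads), 3)
  expect_identical(tads$start_bin, c(0L, 0L, 10L))
  expect_identical(tads$end_bin, c(9L, 19L, 19L))
  expect_identical(tads$length_bins, tads$end_bin - tads$start_bin + 1L)

  region2 <- list(start_bin = 10L, end_bin = 39L,
                  unique_bins = list(c(17L, 25L)))
  tads2 <- enumerate_potential_tads(region2, min_size = 3)
  expect_equal(nrow(tads2), choose(4, 2))
  expect_true(all(tads2$length_bins >= 3))
  expect_true(all(tads2$start_bin >= 10 & tads2$end_bin <= 39))

  # short sub-intervals are dropped by the minimum size
  region3 <- list(start_bin = 0L, end_bin = 9L, unique_bins = list(1L))
  tads3 <- enumerate_potential_tads(region3, min_size = 3)
  expect_false(any(tads3$length_bins < 3))
  expect_equal(nrow(tads3), 2)  # [0,9] and [2,9]; [0,1] is too short
})
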