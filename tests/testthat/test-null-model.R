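make_null <- function(values) {
  structure(list(length_bins = 10L, values = sort(values),
                 N = length(values)),
            class = "null_distribution")
}

test_that("permutation p-value is the strict fraction below", {
  null <- make_null(rep(c(0.2, 0.5, 0.8), 34))  # 102 draws
  expect_equal(permutation_pvalue(0.7, null), 68 / 102)
  # ties do not count: strictly-below convention
  expect_equal(permutation_pvalue(0.5, null), 34 / 102)
  expect_equal(permutation_pvalue(0.1, null), 0)
  expect_equal(permutation_pvalue(0.9, null), 1)
  expect_true(is.na(permutation_pvalue(NA, null)))
  # add-one convention avoids exact zeros
  expect_equal(permutation_pvalue(0.1, null, add_one = TRUE), 1 / 103)
  expect_error(permutation_pvalue(0.5, make_null(runif(50))), "100")
})

test_that("BH adjustment matches the hand-stepped oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # step-up: min over j >= i of p_(j) * m / j = 0.04 for every rank
  expect_equal(bh_adjust(p), rep(0.04, 4))
  withr::with_seed(8, {
    p2 <- runif(50)
    m <- length(p2)
    o <- order(p2)
    q <- rev(cummin(rev(p2[o] * m / seq_len(m))))
    expect_equal(bh_adjust(p2)[o], pmin(q, 1))
  })
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_true(is.na(bh_adjust(c(0.1, NA))[2]))
})

test_that("the similarity filter resets only significant high-SCC tests", {
  p <- c(0.01, 0.01, 0.20, 0.04, NA)
  rho <- c(0.95, 0.50, 0.95, 0.86, 0.9)
  out <- theta_filter(p, rho, alpha = 0.05, theta = 0.85)
  expect_equal(out, c(0.5, 0.01, 0.20, 0.5, NA))
  # boundary cases: p == alpha and rho == theta are both untouched
  expect_equal(theta_filter(0.05, 0.95), 0.05)
  expect_equal(theta_filter(0.01, 0.85), 0.01)
  expect_error(theta_filter(0.01, 0.9, theta = 1))
})

test_that("pseudo-TAD sampling covers each diagonal correctly", {
  pos <- withr::with_seed(2, sample_null_tad(8, n_bins = 50))
  counts <- table(pos$d)
  expect_identical(as.integer(counts), 8:1)
  for (d in 0:7) {
    i <- pos$i[pos$d == d]
    expect_identical(pos$j[pos$d == d], i + d)
    expect_false(anyDuplicated(i) > 0)
    expect_true(all(i >= 0 & i + d <= 49))
  }
  # distance cap trims the deepest diagonals
  pos2 <- withr::with_seed(2, sample_null_tad(8, 50, max_dist = 150000))
  expect_equal(max(pos2$d), 3)
})

test_that("null distributions are reproducible and seed-insulated", {
  M1 <- random_cm(60, lambda = 15, seed = 30)
  M2 <- random_cm(60, lambda = 15, seed = 31)
  a <- null_scc_distribution(M1, M2, 10, N = 150, seed = 4)
  b <- null_scc_distribution(M1, M2, 10, N = 150, seed = 4)
  expect_identical(a$values, b$values)
  expect_s3_class(a, "null_distribution")
  expect_true(all(a$values >= -1 & a$values <= 1))
  expect_lte(a$N, 150)
  # a seeded call does not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(null_scc_distribution(M1, M2, 10, N = 150, seed = 4))
  expect_identical(runif(1), before)
})

test_that("compiled and reference null engines agree statistically", {
  M1 <- random_cm(60, lambda = 15, seed = 32)
  M2 <- random_cm(60, lambda = 15, seed = 33)
  a <- null_scc_distribution(M1, M2, 9, N = 600, seed = 1, engine = "cpp")
  b <- null_scc_distribution(M1, M2, 9, N = 600, seed = 2, engine = "r")
  # same sampling scheme, different streams: compare the distributions
  expect_lt(abs(mean(a$values) - mean(b$values)),
            4 * sqrt(var(a$values) / a$N + var(b$values) / b$N))
  ks <- suppressWarnings(stats::ks.test(a$values, b$values))
  expect_gt(ks$p.value, 0.001)
})

test_that("the fitted null quantile curve tracks the knots", {
  M1 <- random_cm(80, lambda = 15, seed = 34)
  M2 <- random_cm(80, lambda = 15, seed = 35)
  sizes <- c(5L, 8L, 11L, 14L, 17L, 20L)
  nds <- lapply(seq_along(sizes), function(k) {
    null_scc_distribution(M1, M2, sizes[k], N = 300, seed = 10 + k)
  })
  f <- fit_null_quantile_curve(sizes, nds, alpha = 0.05)
  knots <- attr(f, "knots")
  expect_equal(knots$size, as.numeric(sizes))
  # the smooth curve stays close to the empirical quantiles
  expect_lt(max(abs(f(sizes) - knots$quantile)), 0.1)
  # outside the fitted range the curve declines to answer
  expect_true(is.na(f(3)))
  expect_true(is.na(f(25)))
  expect_error(fit_null_quantile_curve(sizes[1:3], nds[1:3]))
})
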