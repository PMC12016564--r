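#' Smooth a contact map with a 2D mean filter
#'
#' Each entry is replaced by the average over the square neighborhood of
#' radius `h` bins, clipped to the matrix (boundary windows shrink rather
#' than being padded, so no counts are fabricated at the edges).  `h = 0`
#' returns the input unchanged.
#'
#' The default radius depends on resolution: finer bins need a wider
#' smoothing window to consolidate domain structure, so `h = 2` below
#' 50-kb resolution and `h = 1` at or above it.
#'
#' @param M A [contact_matrix].
#' @param h Non-negative integer window radius in bins.
#' @return A smoothed [contact_matrix].
#' @export
mean_filter <- function(M, h = default_smooth_h(M$resolution)) {
  stopifnot(inherits(M, "contact_matrix"))
  h <- as.integer(h)
  if (h < 0) stop("`h` must be >= 0")
  if (h >= M$n_bins) stop("`h` must be smaller than the number of bins")
  if (h == 0) return(M)
  sm <- box_mean(M$counts, h)
  # clipped windows are symmetric about the diagonal, so symmetry is
  # preserved up to floating-point noise; enforce it exactly
  sm <- (sm + t(sm)) / 2
  out <- M
  out$counts <- sm
  out
}

#' Default mean-filter radius for a given resolution
#'
#' @param resolution Bin width in bp.
#' @return Integer radius in bins: 2 below 50 kb, else 1.
#' @export
default_smooth_h <- function(resolution) {
  if (resolution < 50000) 2L else 1L
}

# Box average with clipped windows via a summed-area table.
box_mean <- function(m, h) {
  n <- nrow(m)
  # summed-area table padded with a leading zero row/column
  S <- matrix(0, n + 1L, n + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum)
  # S is now t(cumsum2d); transpose back
  S[-1L, -1L] <- t(S[-1L, -1L])
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  # window sum over rows [lo_i, hi_i] x cols [lo_j, hi_j]
  sums <- S[hi + 1L, hi + 1L, drop = FALSE] -
    S[lo, hi + 1L, drop = FALSE] -
    S[hi + 1L, lo, drop = FALSE] +
    S[lo, lo, drop = FALSE]
  counts <- outer(hi - lo + 1L, hi - lo + 1L)
  sums / counts
}

#' Knight-Ruiz balancing of a contact map
#'
#' Finds a positive diagonal scaling `D` such that `D M D` has equal row
#' sums for every row that is not entirely zero; all-zero rows are excluded
#' from balancing and restored as zero.  The balanced matrix is rescaled so
#' that the common row sum equals the mean raw row sum of the included
#' rows, which preserves total mass up to tolerance.
#'
#' The scaling vector is computed with the Knight-Ruiz inner-outer Newton
#' iteration (an inexact Newton method with conjugate-gradient inner
#' solves).  If it fails to converge within `max_iter` inner iterations the
#' function falls back to plain iterative proportional (Sinkhorn) scaling
#' with a warning.
#'
#' @param M A [contact_matrix] with non-negative entries.
#' @param tol Convergence tolerance on the row-sum residual.
#' @param max_iter Maximum number of inner iterations.
#' @return A balanced [contact_matrix].
#' @export
kr_normalize <- function(M, tol = 1e-6, max_iter = 3000) {
  stopifnot(inherits(M, "contact_matrix"))
  A <- M$counts
  keep <- rowSums(A) > 0
  if (sum(keep) < 2) stop("fewer than 2 non-zero rows; cannot balance")
  Ak <- A[keep, keep, drop = FALSE]
  x <- kr_vector(Ak, tol = tol, max_iter = max_iter)
  if (is.null(x)) {
    warning("KR Newton iteration did not converge; ",
            "falling back to iterative proportional scaling")
    x <- sinkhorn_vector(Ak, tol = tol, max_iter = 10 * max_iter)
  }
  B <- Ak * tcrossprod(x)   # diag(x) %*% Ak %*% diag(x), row sums ~ 1
  target <- mean(rowSums(A[keep, , drop = FALSE]))
  out <- matrix(0, nrow(A), ncol(A))
  out[keep, keep] <- B * target
  out <- (out + t(out)) / 2
  res <- M
  res$counts <- out
  res
}

# Knight-Ruiz balancing: returns x with diag(x) A diag(x) row sums == 1,
# or NULL on non-convergence.  Inexact Newton on f(x) = x * (A x) - e with
# CG inner solves, following the standard inner-outer scheme.
kr_vector <- function(A, tol = 1e-6, max_iter = 3000) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3  # clamp box for the scaled iterate
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  mvp <- 0  # matrix-vector products used
  while (rout > rt) {
    k <- 0
    rho_km2 <- NA_real_
    innertol <- max(eta^2 * rout, rt)
    y <- e; Z <- numeric(n); p <- numeric(n)
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      mvp <- mvp + 1
      if (mvp > max_iter) return(NULL)
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + 1
    if (mvp > max_iter) return(NULL)
    # adaptive forcing term
    rat <- rout / rold; rold <- rout
    eta <- g * rat
    if (g * eta^2 > 0.1) eta <- max(eta, g * eta^2)
    eta <- max(min(eta, etamax), 0.5 * sqrt(rt) / sqrt(rout))
  }
  x
}

# Symmetric Sinkhorn scaling toward unit row sums.
sinkhorn_vector <- function(A, tol = 1e-6, max_iter = 30000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- as.vector(A %*% x) * x
    if (max(abs(r - 1)) < tol) return(x)
    x <- x / sqrt(r)
  }
  warning("iterative proportional scaling stopped before tolerance")
  x
}
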