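#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a differential-region result
#'
#' @param x A `diffgr_result`.
#' @param what `"calls"` for the region-level table (default) or
#'   `"tests"` for the per-potential-TAD table.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy diffgr_result
#' @export
tidy.diffgr_result <- function(x, what = c("calls", "tests"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' One-row summary of a differential-region result
#'
#' @param x A `diffgr_result`.
#' @param ... Unused.
#' @return A one-row tibble with region/test counts, the differential
#'   proportion, and the main configuration values.
#' @export
glance.diffgr_result <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x$calls),
    n_tests = nrow(x$tests),
    n_differential = sum(x$calls$differential),
    prop_differential = mean(x$calls$differential),
    alpha = x$config$alpha,
    theta = if (is.numeric(x$config$theta)) x$config$theta else NA_real_,
    nperm = x$config$nperm)
}

#' Plot region-level SCC along the chromosome
#'
#' Each candidate region is drawn at its genomic midpoint with its
#' whole-region SCC; differential regions are highlighted and point shape
#' encodes the candidate type.
#'
#' @param object A `diffgr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffgr_result
#' @export
autoplot.diffgr_result <- function(object, ...) {
  d <- object$calls
  d$mid_mb <- (d$start_bp + d$end_bp) / 2 / 1e6
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid_mb, y = .data$scc,
                                  colour = .data$differential,
                                  shape = .data$kind)) +
    ggplot2::geom_hline(yintercept = if (is.numeric(object$config$theta))
      object$config$theta else NA, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      name = "differential") +
    ggplot2::labs(x = sprintf("%s position (Mb)", object$chrom),
                  y = "local SCC", shape = "candidate type") +
    ggplot2::theme_minimal()
}

#' Heatmap of a contact matrix
#'
#' Log-scaled raster of the contact map, optionally bin-averaged for
#' large matrices so the plot stays light.
#'
#' @param object A [contact_matrix].
#' @param max_px Maximum number of rendered rows/columns; larger matrices
#'   are block-averaged down to this size (default 512).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_matrix
#' @export
autoplot.contact_matrix <- function(object, max_px = 512, ...) {
  m <- object$counts
  n <- nrow(m)
  if (n > max_px) {
    f <- ceiling(n / max_px)
    grp <- (seq_len(n) - 1L) %/% f
    m <- rowsum(t(rowsum(m, grp)), grp) / (f * f)
    step <- object$resolution * f
  } else {
    step <- object$resolution
  }
  d <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  d$x <- (object$offset + (d$j - 1) * step) / 1e6
  d$y <- (object$offset + (d$i - 1) * step) / 1e6
  d$value <- log10(as.vector(m) + 1)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = "log10(count + 1)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = sprintf("%s (Mb)", object$chrom),
                  y = sprintf("%s (Mb)", object$chrom)) +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' @param null A `null_distribution`.
#' @param rho_obs Optional observed SCC drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_null_distribution <- function(null, rho_obs = NULL) {
  stopifnot(inherits(null, "null_distribution"))
  d <- tibble::tibble(rho = null$values)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70",
                            colour = "grey40") +
    ggplot2::labs(
      x = sprintf("null SCC (TAD size %d bins, N = %d)",
                  null$length_bins, null$N),
      y = "count") +
    ggplot2::theme_minimal()
  if (!is.null(rho_obs)) {
    p <- p + ggplot2::geom_vline(xintercept = rho_obs,
                                 colour = "firebrick")
  }
  p
}
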