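#' Construct a binned intra-chromosomal contact matrix
#'
#' A `contact_matrix` wraps a dense symmetric bin-by-bin count (or, after
#' smoothing/balancing, real-valued) matrix together with its genomic
#' metadata.  Bin `b` (0-based) covers the half-open genomic interval
#' `[offset + b * resolution, offset + (b + 1) * resolution)`.
#'
#' @param counts Square numeric matrix of non-negative contact frequencies.
#'   An asymmetric matrix is symmetrized by the elementwise maximum of the
#'   two triangles (with a warning), which tolerates upper-triangle-only
#'   exports.
#' @param resolution Bin width in base pairs.
#' @param chrom Chromosome label.
#' @param offset Genomic coordinate (bp) at which bin 0 starts.
#' @return An object of class `contact_matrix` with elements `counts`,
#'   `resolution`, `chrom`, `offset` and `n_bins`.
#' @examples
#' cm <- contact_matrix(matrix(c(4, 1, 1, 4), 2), resolution = 50000)
#' cm$n_bins
#' @export
contact_matrix <- function(counts, resolution, chrom = "chr1", offset = 0) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("`counts` must be square, got ", nrow(counts), " x ", ncol(counts))
  }
  if (nrow(counts) < 2) stop("a contact matrix needs at least 2 bins")
  if (anyNA(counts)) stop("`counts` contains missing values")
  if (any(counts < 0)) stop("`counts` contains negative entries")
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0) {
    stop("`resolution` must be a single positive number of base pairs")
  }
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    warning("asymmetric counts symmetrized by elementwise max of triangles")
    counts <- pmax(counts, t(counts))
  } else {
    # exact symmetry, not just within tolerance
    counts <- pmax(counts, t(counts))
  }
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, resolution = as.numeric(resolution),
         chrom = chrom, offset = as.numeric(offset), n_bins = nrow(counts)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %s: %d bins @ %s bp (%.3g total counts)\n",
    x$chrom, x$n_bins, format(x$resolution, big.mark = ","),
    sum(x$counts[upper.tri(x$counts, diag = TRUE)])
  ))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

#' Total contact count of a matrix
#'
#' Sum over the upper triangle including the main diagonal, i.e. each
#' locus pair counted once.
#'
#' @param M A [contact_matrix].
#' @return A single number.
#' @export
total_contacts <- function(M) {
  stopifnot(inherits(M, "contact_matrix"))
  sum(M$counts[upper.tri(M$counts, diag = TRUE)])
}

#' Construct a TAD boundary set
#'
#' Boundaries are stored as 0-based indices of the *last* bin of each TAD,
#' so the region between consecutive boundaries `(b_prev, b_next]` is a
#' clean half-open bin interval.  The chromosome end bin is implicitly
#' always a boundary and need not be listed.
#'
#' @param bins Integer vector of boundary bin indices (0-based); sorted and
#'   deduplicated on construction.
#' @param sample_id Label for the sample the boundaries came from.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(bins, sample_id = "sample") {
  bins <- sort(unique(as.integer(bins)))
  if (length(bins) && bins[1] < 0) stop("boundary bin indices must be >= 0")
  structure(list(bins = bins, sample_id = sample_id), class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set> %s: %d boundaries\n", x$sample_id,
              length(x$bins)))
  invisible(x)
}

#' Read a contact matrix from disk
#'
#' Supports three text dialects: `dense` (an n-by-n whitespace-separated
#' numeric grid), `coo` (three columns `bin_i bin_j count`, 0-based bins,
#' each pair given once and mirrored on load), and `cooler` (a
#' bins/pixels-style dump: a `bins` table with `chrom start end` and a
#' `pixels` table with `bin1_id bin2_id count`; the requested chromosome is
#' selected by name).
#'
#' @param path Path to the file.
#' @param format One of `"dense"`, `"coo"`, `"cooler"`.
#' @param resolution Bin width in bp.
#' @param chrom Chromosome label (used to subset `cooler` input).
#' @param n_bins Number of bins; required for `coo` when the matrix has
#'   trailing empty bins, otherwise inferred as `max(bin) + 1`.
#' @param offset Genomic start coordinate of bin 0.
#' @return A [contact_matrix].
#' @export
read_contact_matrix <- function(path, format = c("dense", "coo", "cooler"),
                                resolution, chrom = "chr1", n_bins = NULL,
                                offset = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  counts <- switch(format,
    dense = {
      m <- as.matrix(utils::read.table(path, header = FALSE))
      if (nrow(m) != ncol(m)) {
        stop("dense grid in ", path, " is not square (", nrow(m), " x ",
             ncol(m), ")")
      }
      storage.mode(m) <- "double"
      m
    },
    coo = {
      d <- utils::read.table(path, header = FALSE,
                             col.names = c("i", "j", "x"))
      nb <- if (is.null(n_bins)) max(d$i, d$j) + 1L else as.integer(n_bins)
      bad <- which(d$i < 0 | d$j < 0 | d$i >= nb | d$j >= nb)
      if (length(bad)) {
        stop("bin index out of range [0, ", nb - 1L, "] at line ", bad[1],
             " of ", path)
      }
      if (any(d$x < 0)) {
        stop("negative count at line ", which(d$x < 0)[1], " of ", path)
      }
      m <- matrix(0, nb, nb)
      m[cbind(d$i + 1L, d$j + 1L)] <- d$x
      m[cbind(d$j + 1L, d$i + 1L)] <- d$x
      m
    },
    cooler = read_cooler_dump(path, chrom)
  )
  contact_matrix(counts, resolution = resolution, chrom = chrom,
                 offset = offset)
}

# Cooler-style text dump: '# bins' section (chrom start end, one row per
# bin, genome-wide ids in file order) followed by '# pixels' section
# (bin1_id bin2_id count).  Only the named chromosome is materialized.
read_cooler_dump <- function(path, chrom) {
  lines <- readLines(path)
  bins_at <- grep("^#\\s*bins\\b", lines)
  pix_at <- grep("^#\\s*pixels\\b", lines)
  if (length(bins_at) != 1 || length(pix_at) != 1 || pix_at <= bins_at) {
    stop("cooler dump must contain a '# bins' then a '# pixels' section")
  }
  bins <- utils::read.table(
    text = lines[(bins_at + 1):(pix_at - 1)],
    col.names = c("chrom", "start", "end")
  )
  pix <- utils::read.table(
    text = lines[(pix_at + 1):length(lines)],
    col.names = c("bin1_id", "bin2_id", "count")
  )
  sel <- which(bins$chrom == chrom)
  if (!length(sel)) stop("chromosome ", chrom, " not present in ", path)
  lo <- min(sel) - 1L  # 0-based id of the chromosome's first bin
  hi <- max(sel) - 1L
  nb <- length(sel)
  keep <- pix$bin1_id >= lo & pix$bin1_id <= hi &
    pix$bin2_id >= lo & pix$bin2_id <= hi
  pix <- pix[keep, , drop = FALSE]
  m <- matrix(0, nb, nb)
  i <- pix$bin1_id - lo + 1L
  j <- pix$bin2_id - lo + 1L
  m[cbind(i, j)] <- pix$count
  m[cbind(j, i)] <- pix$count
  m
}

#' Read TAD boundaries from disk
#'
#' `bed` input carries one interval per TAD; each interval's end coordinate
#' `e` maps to the last-bin index `(e - offset) / resolution - 1` (floored
#' when not a multiple of the resolution).  `twocol` input carries
#' `chrom bin` rows with 0-based bin indices.  Boundaries are sorted and
#' deduplicated after mapping.
#'
#' @param path Path to the file.
#' @param format `"bed"` or `"twocol"`.
#' @param resolution Bin width in bp.
#' @param offset Genomic start coordinate of bin 0.
#' @param n_bins If given, boundaries at or beyond `n_bins` raise an error.
#' @param sample_id Label stored on the returned set.
#' @return A [boundary_set].
#' @export
read_boundaries <- function(path, format = c("bed", "twocol"), resolution,
                            offset = 0, n_bins = NULL,
                            sample_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  bins <- switch(format,
    bed = {
      d <- utils::read.table(path, header = FALSE)
      if (ncol(d) < 3) stop("BED input needs at least 3 columns")
      floor((d[[3]] - offset) / resolution) - 1 +
        (((d[[3]] - offset) %% resolution) > 0)
    },
    twocol = {
      d <- utils::read.table(path, header = FALSE)
      if (ncol(d) < 2) stop("twocol input needs chrom and bin columns")
      d[[2]]
    }
  )
  bins <- sort(unique(as.integer(bins)))
  if (length(bins) && bins[1] < 0) {
    stop("boundary maps to a negative bin index; check `offset`")
  }
  if (!is.null(n_bins) && length(bins) && max(bins) >= n_bins) {
    stop("boundary bin ", max(bins), " out of range for ", n_bins, " bins")
  }
  boundary_set(bins, sample_id = sample_id)
}

#' Write region-level differential calls to a TSV file
#'
#' One row per candidate region, tab-separated with a header line.
#' Genomic coordinates are half-open base-pair intervals.
#'
#' @param calls Tibble of region calls as produced by [run_diffgr()] (the
#'   `calls` element, or `tidy()` of the result).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a region-call table written by [write_region_calls()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per candidate region.
#' @export
read_region_calls <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write a contact matrix as COO triplet text
#'
#' Upper triangle (including the diagonal) of the nonzero entries, 0-based
#' bin indices, one `i j count` row per pair.
#'
#' @param M A [contact_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(M, path) {
  stopifnot(inherits(M, "contact_matrix"))
  up <- which(upper.tri(M$counts, diag = TRUE) & M$counts != 0,
              arr.ind = TRUE)
  d <- data.frame(i = up[, 1] - 1L, j = up[, 2] - 1L,
                  x = M$counts[up])
  d <- d[order(d$i, d$j), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
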