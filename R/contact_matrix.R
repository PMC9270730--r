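#' Banded sparse Hi-C contact matrix
#'
#' Container for a symmetric per-chromosome Hi-C contact matrix restricted to
#' a diagonal band. Only the upper triangle is stored; entries are given as
#' 0-based bin index pairs `(i, j)` with `i <= j` and genomic distance
#' `d = j - i` limited to `[min_band, max_band]` bins. Analysis values
#' (`value`) may be balancing-corrected while the uncorrected counts (`raw`)
#' are carried alongside for the raw interaction-count filter.
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in base pairs.
#' @param n_bins Number of bins; the matrix is conceptually
#'   `n_bins x n_bins`.
#' @param i,j 0-based bin indices. Entries in the lower triangle are folded
#'   onto the upper triangle.
#' @param value Analysis values (balanced counts when `balanced = TRUE`).
#' @param raw Uncorrected interaction counts; defaults to `value`.
#' @param balanced Logical flag, whether `value` is correction-weighted.
#' @param min_band,max_band Band limits in bins; entries outside the band
#'   are dropped.
#'
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(chrom, bin_size, n_bins, i, j, value,
                           raw = value, balanced = FALSE,
                           min_band = 0L, max_band = n_bins - 1L) {
  stopifnot(length(chrom) == 1L, bin_size > 0, n_bins >= 1)
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j) || length(i) != length(value))
    stop("i, j and value must have equal length", call. = FALSE)
  if (length(raw) != length(value))
    stop("raw must have the same length as value", call. = FALSE)
  if (any(!is.finite(value)) || any(value < 0) ||
      any(!is.finite(raw)) || any(raw < 0))
    stop_nbloop("value","contact values must be finite and >= 0")
  if (any(i < 0L | i >= n_bins | j < 0L | j >= n_bins))
    stop_nbloop("value","bin indices out of [0, n_bins)")
  # fold lower triangle onto the upper triangle
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  if (anyDuplicated(paste(i, j)))
    stop_nbloop("value","duplicate (i, j) entries")
  d <- j - i
  keep <- d >= min_band & d <= max_band
  ord <- order(d[keep], i[keep])
  structure(
    list(chrom = chrom, bin_size = as.numeric(bin_size),
         n_bins = as.integer(n_bins),
         i = i[keep][ord], j = j[keep][ord],
         value = as.numeric(value[keep][ord]),
         raw = as.numeric(raw[keep][ord]),
         balanced = isTRUE(balanced),
         min_band = as.integer(min_band), max_band = as.integer(max_band)),
    class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<%s> %s: %d bins @ %g bp, %d stored entries, band [%d, %d] bins%s\n",
              class(x)[1L], x$chrom, x$n_bins, x$bin_size, length(x$i),
              x$min_band, x$max_band,
              if (x$balanced) ", balanced" else ", raw"))
  invisible(x)
}

#' Number of stored entries
#' @param x A `contact_matrix`.
#' @export
n_entries <- function(x) length(x$i)

# Restrict the stored band of a contact matrix to [min_band, max_band] bins.
restrict_band <- function(x, min_band, max_band) {
  d <- x$j - x$i
  keep <- d >= min_band & d <= max_band
  x$i <- x$i[keep]; x$j <- x$j[keep]
  x$value <- x$value[keep]; x$raw <- x$raw[keep]
  x$min_band <- as.integer(max(min_band, x$min_band))
  x$max_band <- as.integer(min(max_band, x$max_band))
  x
}

# Symmetric sparse lookup matrix (1-based) built from the stored upper
# triangle; unstored in-band positions read as 0, which matches the sparse
# semantics of the banded store.
symmetric_lookup <- function(x) {
  off <- x$i != x$j
  Matrix::sparseMatrix(i = c(x$i, x$j[off]) + 1L,
                       j = c(x$j, x$i[off]) + 1L,
                       x = c(x$value, x$value[off]),
                       dims = c(x$n_bins, x$n_bins))
}

# Namespaced condition helper: all user-facing errors carry a class
# "nbloop_<what>_error" so callers/tests can match them by name.
stop_nbloop <- function(what, msg, ...) {
  stop(structure(class = c(paste0("nbloop_", what, "_error"),
                           "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
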