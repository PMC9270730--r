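#' Per-distance expected contact values
#'
#' Computes the expected contact value for every genomic distance `d` in the
#' stored band, under one of three definitions:
#' \describe{
#'   \item{`nonzero`}{sum of values at `d` divided by the number of nonzero
#'     entries at `d` (sparsity-robust; the default downstream).}
#'   \item{`all`}{sum of values at `d` divided by all `n_bins - d` positions
#'     at `d`, zeros included.}
#'   \item{`ligation`}{the nonzero expected value modulated per element by
#'     the coverage product `rowsum_i * rowsum_j / total_sum`, correcting
#'     for unevenly distributed ligation events (HOMER-style). Row sums are
#'     genuine marginals of the symmetric banded matrix: each off-diagonal
#'     entry contributes to both of its rows.}
#' }
#' Distances whose entries are all zero carry no expected value (`NA`) and
#' are skipped downstream rather than forcing a division by zero.
#'
#' @param mat A [contact_matrix()], non-empty in its band.
#' @param mode One of `"nonzero"`, `"all"`, `"ligation"`.
#' @return An object of class `expected_profile`.
#' @export
compute_expected <- function(mat, mode = c("nonzero", "all", "ligation")) {
  mode <- match.arg(mode)
  if (!length(mat$i)) stop_nbloop("value", "matrix has no entries in band")
  d <- mat$j - mat$i
  dd <- mat$min_band:mat$max_band
  fd <- factor(d, levels = dd)
  sum_d <- as.numeric(tapply(mat$value, fd, sum, default = 0))
  n_nonzero <- as.numeric(tapply(mat$value > 0, fd, sum, default = 0))
  n_all <- mat$n_bins - dd
  exp_nonzero <- ifelse(n_nonzero > 0, sum_d / n_nonzero, NA_real_)
  exp_all <- ifelse(n_nonzero > 0, sum_d / n_all, NA_real_)
  prof <- list(mode = mode, chrom = mat$chrom, bin_size = mat$bin_size,
               n_bins = mat$n_bins, min_band = mat$min_band,
               max_band = mat$max_band, d = dd,
               exp_d = if (mode == "all") exp_all else exp_nonzero,
               n_nonzero = n_nonzero, n_all = n_all,
               row_sums = NULL, total_sum = NULL)
  if (mode == "ligation") {
    rs <- numeric(mat$n_bins)
    agg_i <- rowsum(mat$value, mat$i)
    rs[as.integer(rownames(agg_i)) + 1L] <- agg_i[, 1L]
    off <- mat$i != mat$j
    if (any(off)) {
      agg_j <- rowsum(mat$value[off], mat$j[off])
      rs[as.integer(rownames(agg_j)) + 1L] <-
        rs[as.integer(rownames(agg_j)) + 1L] + agg_j[, 1L]
    }
    total <- sum(rs)
    if (total <= 0) stop_nbloop("total", "total matrix sum is zero")
    prof$row_sums <- rs
    prof$total_sum <- total
  }
  class(prof) <- "expected_profile"
  prof
}

#' @export
print.expected_profile <- function(x, ...) {
  cat(sprintf("<expected_profile> mode=%s, %s, distances %d..%d (%d with data)\n",
              x$mode, x$chrom, x$min_band, x$max_band, sum(!is.na(x$exp_d))))
  invisible(x)
}

# Per-entry expected value for stored entries (i, j, d vectors, 0-based).
expected_for <- function(profile, i, j, d) {
  e <- profile$exp_d[d - profile$min_band + 1L]
  if (profile$mode == "ligation") {
    e <- e * profile$row_sums[i + 1L] * profile$row_sums[j + 1L] /
      profile$total_sum
  }
  e
}

#' Observed/expected transformation
#'
#' Divides every stored contact value by its expected value at the same
#' genomic distance (per-element in `ligation` mode), removing the distance
#' decay. Entries at distances without an expected value are dropped; zero
#' contacts map to zero.
#'
#' @param mat A [contact_matrix()].
#' @param profile An `expected_profile` computed from the same geometry.
#' @return An object of class `obs_exp_matrix` (a `contact_matrix` whose
#'   `value` field holds observed/expected ratios; `raw` is carried along).
#' @export
transform_obs_exp <- function(mat, profile) {
  if (!inherits(profile, "expected_profile"))
    stop("profile must be an expected_profile", call. = FALSE)
  if (mat$n_bins != profile$n_bins || mat$bin_size != profile$bin_size ||
      !identical(mat$chrom, profile$chrom))
    stop_nbloop("geometry", "matrix and expected profile geometry differ")
  d <- mat$j - mat$i
  e <- expected_for(profile, mat$i, mat$j, d)
  keep <- !is.na(e) & e > 0
  out <- mat
  out$i <- mat$i[keep]; out$j <- mat$j[keep]
  out$value <- mat$value[keep] / e[keep]
  out$raw <- mat$raw[keep]
  out$expected_mode <- profile$mode
  class(out) <- c("obs_exp_matrix", "contact_matrix")
  out
}
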