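#' Match loop anchors against protein-peak intervals
#'
#' Bins the peak intervals to the loop bin size and accepts a loop as
#' matched iff **both** anchor bins contain at least one binned peak (the
#' both-loci rule used for CTCF correlation of loop calls). Loops on
#' chromosomes absent from the peak set trigger a warning and count as
#' unmatched.
#'
#' @param loops A `loop_calls` data frame.
#' @param peaks Data frame of intervals (`chrom`, `start`, `end`), e.g.
#'   from [read_intervals_bed()].
#' @param bin_size Bin size in base pairs.
#' @return An object of class `match_report`: list with `n_loops`,
#'   `n_matched`, `fraction`.
#' @export
anchors_match_intervals <- function(loops, peaks, bin_size) {
  n_loops <- nrow(loops)
  if (n_loops == 0)
    return(structure(list(n_loops = 0L, n_matched = 0L, fraction = NA_real_),
                     class = "match_report"))
  peak_bins <- new.env(parent = emptyenv())
  if (nrow(peaks)) {
    for (ch in unique(peaks$chrom)) {
      p <- peaks[peaks$chrom == ch, , drop = FALSE]
      bins <- unlist(Map(function(s, e)
        seq.int(floor(s / bin_size), floor((e - 1) / bin_size)),
        p$start, p$end))
      assign(ch, unique(bins), envir = peak_bins)
    }
  }
  missing_chroms <- setdiff(unique(loops$chrom), ls(peak_bins))
  if (length(missing_chroms) && nrow(peaks))
    warning(sprintf("no peaks on chromosome(s) %s; loops there unmatched",
                    paste(missing_chroms, collapse = ", ")), call. = FALSE)
  matched <- vapply(seq_len(n_loops), function(k) {
    ch <- loops$chrom[k]
    if (!exists(ch, envir = peak_bins, inherits = FALSE)) return(FALSE)
    bins <- get(ch, envir = peak_bins)
    (loops$bin_i[k] %in% bins) && (loops$bin_j[k] %in% bins)
  }, logical(1L))
  structure(list(n_loops = n_loops, n_matched = sum(matched),
                 fraction = sum(matched) / n_loops),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> %d/%d loops with both anchors on a peak (%.3f)\n",
              x$n_matched, x$n_loops,
              if (is.na(x$fraction)) NA else x$fraction))
  invisible(x)
}

#' Intersect two loop sets
#'
#' Greedy one-to-one matching of loop centers within a Chebyshev bin
#' tolerance, in genomic position order.
#'
#' @param a,b Loop data frames (`bin_i`/`bin_j` or `i`/`j` columns).
#' @param tol_bins Chebyshev matching tolerance in bins (0 = exact bin).
#' @return List with `n_a`, `n_b`, `n_intersect`.
#' @export
intersect_loop_sets <- function(a, b, tol_bins = 0) {
  ai <- a$bin_i %||% a$i; aj <- a$bin_j %||% a$j
  bi <- b$bin_i %||% b$i; bj <- b$bin_j %||% b$j
  m <- greedy_match(ai, aj, bi, bj, tol_bins)
  list(n_a = length(ai), n_b = length(bi), n_intersect = length(m$a))
}

#' Two-sided two-proportion z-test
#'
#' Pooled two-proportion z statistic
#' \deqn{z = (x_1/n_1 - x_2/n_2) / \sqrt{\hat p (1-\hat p)(1/n_1+1/n_2)}}
#' with \eqn{\hat p = (x_1+x_2)/(n_1+n_2)}, and its two-sided normal
#' p-value. A degenerate pooled proportion (0 or 1) returns `z = 0`,
#' `p = 1` by convention.
#'
#' @param x1,x2 Success counts.
#' @param n1,n2 Trial counts (`> 0`).
#' @return List with `z` and `p_two_sided`.
#' @export
proportion_z_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop_nbloop("domain", "n1 and n2 must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2)
    stop_nbloop("domain", "require 0 <= x <= n")
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) return(list(z = 0, p_two_sided = 1))
  z <- (x1 / n1 - x2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p_two_sided = 2 * stats::pnorm(-abs(z)))
}

#' Aggregate observed/expected submatrices around loops
#'
#' Elementwise mean of the `(2*half_width+1)^2` observed/expected
#' submatrices centered on each loop (loop pileup). Loops whose window
#' leaves the matrix or the distance band are skipped and counted.
#'
#' @param obsexp An `obs_exp_matrix`.
#' @param loops Loop data frame (`bin_i`/`bin_j` or `i`/`j`).
#' @param half_width Window inradius in bins.
#' @return The mean submatrix, with attributes `n_used` and `n_skipped`.
#' @export
aggregate_loop_submatrices <- function(obsexp, loops, half_width) {
  li <- loops$bin_i %||% loops$i
  lj <- loops$bin_j %||% loops$j
  if (!length(li)) stop_nbloop("no_loops", "no loops to aggregate")
  h <- as.integer(half_width)
  lookup <- symmetric_lookup(obsexp)
  acc <- matrix(0, 2L * h + 1L, 2L * h + 1L)
  used <- 0L
  off <- expand.grid(da = -h:h, db = -h:h)
  for (k in seq_along(li)) {
    a <- li[k] + off$da; b <- lj[k] + off$db
    dist <- abs(b - a)
    if (any(a < 0 | b < 0 | a >= obsexp$n_bins | b >= obsexp$n_bins |
            dist < obsexp$min_band | dist > obsexp$max_band))
      next
    acc <- acc + matrix(lookup[cbind(a + 1L, b + 1L)], 2L * h + 1L)
    used <- used + 1L
  }
  if (used == 0L)
    stop_nbloop("no_loops", "no loop window fits inside the band")
  out <- acc / used
  attr(out, "n_used") <- used
  attr(out, "n_skipped") <- length(li) - used
  out
}
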