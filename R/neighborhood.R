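#' Pool candidates per neighborhood
#'
#' Within one neighborhood only the candidate with the highest
#' observed/expected value is kept as the representative; all candidates
#' within Chebyshev distance `window_size` of a stronger one are absorbed.
#' Ties break deterministically: higher `obs_exp`, then smaller distance
#' `d`, then smaller `i`. The operation is idempotent.
#'
#' @param candidates Candidate data frame from [select_candidates()].
#' @param window_size Neighborhood inradius in bins.
#' @return The surviving representatives, sorted by (d, i).
#' @export
pool_candidates <- function(candidates, window_size) {
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  ord <- order(-candidates$obs_exp, candidates$d, candidates$i)
  ci <- candidates$i[ord]; cj <- candidates$j[ord]
  keep_i <- numeric(0); keep_j <- numeric(0); keep_idx <- integer(0)
  for (k in seq_len(n)) {
    if (length(keep_i) == 0L ||
        all(pmax(abs(ci[k] - keep_i), abs(cj[k] - keep_j)) > window_size)) {
      keep_i <- c(keep_i, ci[k]); keep_j <- c(keep_j, cj[k])
      keep_idx <- c(keep_idx, ord[k])
    }
  }
  out <- candidates[sort(keep_idx), , drop = FALSE]
  out <- out[order(out$d, out$i), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$stage_counts <- attr(candidates, "stage_counts")
  out
}

#' Extract a donut neighborhood around a candidate
#'
#' The window is the `(2*window_size+1)^2` square centered on the
#' candidate; the peak is the inner `(2*peak_width+1)^2` square. The
#' remaining window cells are partitioned into test regions by their
#' offsets `(da, db)` from the center (`a` indexes rows/first anchor, `b`
#' columns/second anchor):
#' \describe{
#'   \item{horizontal}{`|da| > peak_width`, `|db| <= peak_width` -- the
#'     cells directly above and below the peak;}
#'   \item{vertical}{`|da| <= peak_width`, `|db| > peak_width` -- the cells
#'     directly left and right of the peak;}
#'   \item{corner}{`da > peak_width`, `db < -peak_width` -- the bottom-left
#'     corner block (toward the main diagonal).}
#' }
#' The remaining three window corners belong to no test region but do
#' count toward `all_background` (every non-peak window cell), which feeds
#' the mean filter. Positions missing from the sparse store read as zero;
#' positions outside the matrix or outside the distance band are truncated
#' (absent, not zero). A neighborhood whose background falls below
#' `min_background_elements`, or with an empty test region, is flagged
#' untestable.
#'
#' @param obsexp An `obs_exp_matrix`.
#' @param center Length-2 vector `c(i, j)` of 0-based bin indices.
#' @param peak_width,window_size Inradii in bins.
#' @param min_background_elements Minimum background size.
#' @param lookup Optional prebuilt symmetric sparse lookup (internal reuse).
#' @return An object of class `neighborhood` with value vectors `peak`,
#'   `horizontal`, `vertical`, `corner`, `all_background`, the center, the
#'   window cell count and a `testable` flag (plus `reason` if not).
#' @export
extract_neighborhood <- function(obsexp, center, peak_width, window_size,
                                 min_background_elements = 25,
                                 lookup = NULL) {
  stopifnot(length(center) == 2L, peak_width < window_size)
  if (is.null(lookup)) lookup <- symmetric_lookup(obsexp)
  w <- window_size; pw <- peak_width
  off <- expand.grid(da = -w:w, db = -w:w)
  a <- center[1L] + off$da
  b <- center[2L] + off$db
  dist <- abs(b - a)
  valid <- a >= 0 & b >= 0 & a < obsexp$n_bins & b < obsexp$n_bins &
    dist >= obsexp$min_band & dist <= obsexp$max_band
  da <- off$da[valid]; db <- off$db[valid]
  vals <- lookup[cbind(a[valid] + 1L, b[valid] + 1L)]
  in_peak <- abs(da) <= pw & abs(db) <= pw
  horiz <- abs(da) > pw & abs(db) <= pw
  vert <- abs(da) <= pw & abs(db) > pw
  corner <- da > pw & db < -pw
  nb <- list(center = center,
             peak = vals[in_peak],
             horizontal = vals[horiz],
             vertical = vals[vert],
             corner = vals[corner],
             all_background = vals[!in_peak],
             n_window = sum(valid))
  empty_region <- !length(nb$horizontal) || !length(nb$vertical) ||
    !length(nb$corner)
  nb$testable <- length(nb$peak) > 0L && !empty_region &&
    length(nb$all_background) >= min_background_elements
  if (!nb$testable)
    nb$reason <- if (empty_region || !length(nb$peak)) "empty_region"
                 else "background_too_small"
  class(nb) <- "neighborhood"
  nb
}

# One-sided rank-sum p-value, alternative "x stochastically greater than y".
# Exact distribution when both groups have <= 25 values and no ties occur;
# otherwise the normal approximation with tie and continuity correction.
# All-equal input carries no rank separation: p = 1.
rank_sum_p <- function(x, y) {
  all_v <- c(x, y)
  if (length(unique(all_v)) == 1L) return(1)
  exact <- length(x) <= 25L && length(y) <= 25L &&
    !any(duplicated(all_v))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                       correct = TRUE)$p.value)
}

#' Evaluate a neighborhood: mean filter plus three rank-sum tests
#'
#' A candidate is rejected outright if
#' `mean(all_background) >= mean(peak)` (a singular outlier is not a
#' loop). Otherwise the peak is tested one-sidedly (alternative: peak
#' stochastically greater) against the horizontal, vertical and corner
#' regions with Wilcoxon rank-sum tests; the candidate is accepted iff all
#' three p-values fall below `p_value`. No multiple-testing correction is
#' applied: each test must individually pass.
#'
#' @param nb A `neighborhood` from [extract_neighborhood()].
#' @param p_value Per-test significance level.
#' @return A list with `accepted`, `p_horizontal`, `p_vertical`,
#'   `p_corner`, and `reason` when rejected before testing.
#' @export
evaluate_neighborhood <- function(nb, p_value = 0.025) {
  if (!isTRUE(nb$testable))
    return(list(accepted = FALSE, p_horizontal = NA_real_,
                p_vertical = NA_real_, p_corner = NA_real_,
                reason = nb$reason %||% "untestable"))
  if (mean(nb$all_background) >= mean(nb$peak))
    return(list(accepted = FALSE, p_horizontal = NA_real_,
                p_vertical = NA_real_, p_corner = NA_real_,
                reason = "mean_filter"))
  ph <- rank_sum_p(nb$peak, nb$horizontal)
  pv <- rank_sum_p(nb$peak, nb$vertical)
  pc <- rank_sum_p(nb$peak, nb$corner)
  list(accepted = ph < p_value && pv < p_value && pc < p_value,
       p_horizontal = ph, p_vertical = pv, p_corner = pc,
       reason = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
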