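#' Loop-calling configuration
#'
#' Bundles all tunable parameters of the detection pipeline with the
#' tool's defaults: `peak_width` 2 and `window_size` 5 (inradii: a square
#' of inradius w spans `2w+1` bins per side), preselection p-value 0.1,
#' rank-sum significance 0.025, minimum raw interaction count 10 and
#' observed/expected threshold 1.5 (used both for prefit thinning and as
#' the candidate gate).
#'
#' @param peak_width Inradius of the peak square, in bins.
#' @param window_size Inradius of the neighborhood window, in bins; must
#'   exceed `peak_width`.
#' @param p_value_preselection Per-distance right-tail p-value threshold
#'   for candidate preselection.
#' @param p_value Significance level each of the three rank-sum tests must
#'   individually beat.
#' @param peak_interaction_threshold Minimum uncorrected interaction count
#'   of a candidate pixel.
#' @param obs_exp_threshold Minimum observed/expected value of a candidate;
#'   also the prefit thinning threshold for distance-model fitting.
#' @param expected_mode Expected-value definition, see [compute_expected()].
#' @param min_distance Minimum anchor distance in base pairs; `NULL` means
#'   4 bins (near-diagonal pairs have intrinsically high counts and are
#'   excluded).
#' @param max_distance Maximum anchor distance in base pairs (default 2 Mb).
#' @param threads Worker count for neighborhood evaluation; results are
#'   independent of this value.
#' @param min_background_elements Minimum background size of a testable
#'   neighborhood after truncation at matrix/band borders.
#' @param min_fit_values Minimum number of values to fit a distance model.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(peak_width = 2, window_size = 5,
                        p_value_preselection = 0.1, p_value = 0.025,
                        peak_interaction_threshold = 10,
                        obs_exp_threshold = 1.5,
                        expected_mode = c("nonzero", "all", "ligation"),
                        min_distance = NULL, max_distance = 2e6,
                        threads = 1, min_background_elements = 25,
                        min_fit_values = 100) {
  expected_mode <- match.arg(expected_mode)
  cfg <- list(peak_width = as.integer(peak_width),
              window_size = as.integer(window_size),
              p_value_preselection = p_value_preselection,
              p_value = p_value,
              peak_interaction_threshold = peak_interaction_threshold,
              obs_exp_threshold = obs_exp_threshold,
              expected_mode = expected_mode,
              min_distance = min_distance, max_distance = max_distance,
              threads = as.integer(threads),
              min_background_elements = as.integer(min_background_elements),
              min_fit_values = as.integer(min_fit_values))
  if (cfg$peak_width < 1L)
    stop_nbloop("config", "peak_width must be >= 1")
  if (cfg$peak_width >= cfg$window_size)
    stop_nbloop("config", "peak_width (%d) must be smaller than window_size (%d)",
                cfg$peak_width, cfg$window_size)
  if (cfg$p_value_preselection <= 0 || cfg$p_value_preselection >= 1 ||
      cfg$p_value <= 0 || cfg$p_value >= 1)
    stop_nbloop("config", "p-value thresholds must lie in (0, 1)")
  if (cfg$peak_interaction_threshold < 0 || cfg$obs_exp_threshold < 0)
    stop_nbloop("config", "thresholds must be non-negative")
  if (!is.null(cfg$min_distance) && cfg$min_distance < 0)
    stop_nbloop("config", "min_distance must be >= 0")
  if (!is.null(cfg$min_distance) && cfg$max_distance < cfg$min_distance)
    stop_nbloop("config", "max_distance must be >= min_distance")
  if (cfg$threads < 1L) stop_nbloop("config", "threads must be >= 1")
  if (cfg$min_background_elements < 1L)
    stop_nbloop("config", "min_background_elements must be >= 1")
  class(cfg) <- "loop_config"
  cfg
}

#' @export
print.loop_config <- function(x, ...) {
  cat("<loop_config>\n")
  for (k in names(x))
    cat(sprintf("  %-26s %s\n", k,
                if (is.null(x[[k]])) "(default)" else format(x[[k]])))
  invisible(x)
}

#' Strict candidate selection
#'
#' A pixel `(i, j)` is a candidate iff its genomic distance carries a
#' fitted model, its observed/expected value is at least
#' `obs_exp_threshold`, its right-tail p-value under the distance model is
#' below `p_value_preselection`, and its uncorrected interaction count is
#' at least `peak_interaction_threshold`. The attribute `stage_counts`
#' records the surviving pixel count after each successive filter.
#'
#' @param obsexp An `obs_exp_matrix` (carries raw counts alongside).
#' @param models A `model_set` fitted on the same matrix.
#' @param config A [loop_config()].
#' @return A data frame (`i`, `j`, `d`, `obs_exp`, `raw`, `p_preselect`)
#'   sorted by (d, i), with attribute `stage_counts`.
#' @export
select_candidates <- function(obsexp, models, config = loop_config()) {
  if (!inherits(config, "loop_config")) config <- do.call(loop_config, config)
  d <- obsexp$j - obsexp$i
  n0 <- length(d)
  has_model <- as.character(d) %in% names(models)
  # p-values, vectorized per distance
  pv <- rep(NA_real_, n0)
  for (dd in names(models)) {
    sel <- d == as.integer(dd)
    if (any(sel)) pv[sel] <- cnb_pvalue(obsexp$value[sel], models[[dd]])
  }
  pass_model <- has_model
  pass_p <- pass_model & pv < config$p_value_preselection
  pass_oe <- pass_p & obsexp$value >= config$obs_exp_threshold
  pass_raw <- pass_oe & obsexp$raw >= config$peak_interaction_threshold
  counts <- c(pixels = n0, with_model = sum(pass_model),
              preselected = sum(pass_p), obs_exp = sum(pass_oe),
              raw_count = sum(pass_raw))
  keep <- which(pass_raw)
  out <- data.frame(i = obsexp$i[keep], j = obsexp$j[keep], d = d[keep],
                    obs_exp = obsexp$value[keep], raw = obsexp$raw[keep],
                    p_preselect = pv[keep])
  out <- out[order(out$d, out$i), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- counts
  out
}
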