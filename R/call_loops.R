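empty_loop_calls <- function(chrom = character(0), bin_size = NA_real_,
                             config = NULL, stage_counts = NULL) {
  out <- data.frame(chrom = character(0), bin_i = integer(0),
                    bin_j = integer(0), start1 = integer(0),
                    end1 = integer(0), start2 = integer(0),
                    end2 = integer(0), obs_exp = numeric(0),
                    raw_count = numeric(0), p_preselect = numeric(0),
                    p_horizontal = numeric(0), p_vertical = numeric(0),
                    p_corner = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("loop_calls", "data.frame")
  attr(out, "bin_size") <- bin_size
  attr(out, "config") <- config
  attr(out, "stage_counts") <- stage_counts
  out
}

#' Detect chromatin loops in a Hi-C contact matrix
#'
#' End-to-end detection on one chromosome: expected-value profile,
#' observed/expected transformation, per-distance continuous negative
#' binomial fits, strict candidate selection, neighborhood pooling, and
#' donut evaluation (mean filter plus three one-sided rank-sum tests).
#' The result is invariant to `config$threads`; anchors are reported as
#' single bins `[bin * bin_size, (bin + 1) * bin_size)`.
#'
#' @param mat A [contact_matrix()] (balanced values as the analysis
#'   substrate; raw counts feed the interaction-height filter).
#' @param config A [loop_config()].
#' @return An object of class `loop_calls`: a data frame of accepted loops
#'   sorted by (bin_i, bin_j) with columns `chrom`, `bin_i`, `bin_j`,
#'   anchor coordinates, `obs_exp`, `raw_count` and the four p-values.
#'   Attributes: `config`, `stage_counts` (pixel/candidate counts after
#'   each successive filter stage), `bin_size`.
#' @export
call_loops <- function(mat, config = loop_config()) {
  if (!inherits(config, "loop_config")) config <- do.call(loop_config, config)
  min_bp <- config$min_distance %||% (4 * mat$bin_size)
  min_bins <- as.integer(ceiling(min_bp / mat$bin_size))
  max_bins <- as.integer(floor(config$max_distance / mat$bin_size))
  if ((2L * config$window_size + 1L)^2 < 250)
    warning(sprintf(
      "window_size %d gives only %d neighborhood elements; at least ~250-300 are advisable",
      config$window_size, (2L * config$window_size + 1L)^2), call. = FALSE)
  mat <- restrict_band(mat, min_bins, max_bins)
  if (!length(mat$i))
    return(empty_loop_calls(bin_size = mat$bin_size, config = config))
  profile <- compute_expected(mat, mode = config$expected_mode)
  obsexp <- transform_obs_exp(mat, profile)
  models <- fit_all_distances(obsexp,
                              prefit_threshold = config$obs_exp_threshold,
                              min_n = config$min_fit_values)
  if (!length(models)) {
    warning("no fittable genomic distances; returning no loops", call. = FALSE)
    return(empty_loop_calls(bin_size = mat$bin_size, config = config))
  }
  cands <- select_candidates(obsexp, models, config)
  counts <- attr(cands, "stage_counts")
  pooled <- pool_candidates(cands, config$window_size)
  counts <- c(counts, pooled = nrow(pooled))
  if (!nrow(pooled))
    return(empty_loop_calls(bin_size = mat$bin_size, config = config,
                            stage_counts = c(counts, mean_filter = 0L,
                                             rank_sum = 0L)))
  lookup <- symmetric_lookup(obsexp)
  eval_one <- function(k) {
    nb <- extract_neighborhood(
      obsexp, c(pooled$i[k], pooled$j[k]), config$peak_width,
      config$window_size, config$min_background_elements, lookup = lookup)
    evaluate_neighborhood(nb, config$p_value)
  }
  ks <- seq_len(nrow(pooled))
  res <- if (config$threads > 1L) {
    parallel::mclapply(ks, eval_one, mc.cores = config$threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(ks, eval_one)
  }
  past_mean <- !vapply(res, function(r) identical(r$reason, "mean_filter") ||
                         identical(r$reason, "untestable") ||
                         identical(r$reason, "empty_region") ||
                         identical(r$reason, "background_too_small"),
                       logical(1L))
  accepted <- vapply(res, function(r) isTRUE(r$accepted), logical(1L))
  counts <- c(counts, mean_filter = sum(past_mean), rank_sum = sum(accepted))
  keep <- which(accepted)
  bs <- mat$bin_size
  out <- data.frame(
    chrom = rep(mat$chrom, length(keep)),
    bin_i = pooled$i[keep], bin_j = pooled$j[keep],
    start1 = as.integer(pooled$i[keep] * bs),
    end1 = as.integer((pooled$i[keep] + 1L) * bs),
    start2 = as.integer(pooled$j[keep] * bs),
    end2 = as.integer((pooled$j[keep] + 1L) * bs),
    obs_exp = pooled$obs_exp[keep], raw_count = pooled$raw[keep],
    p_preselect = pooled$p_preselect[keep],
    p_horizontal = vapply(res[keep], `[[`, 0, "p_horizontal"),
    p_vertical = vapply(res[keep], `[[`, 0, "p_vertical"),
    p_corner = vapply(res[keep], `[[`, 0, "p_corner"),
    stringsAsFactors = FALSE)
  out <- out[order(out$bin_i, out$bin_j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("loop_calls", "data.frame")
  attr(out, "bin_size") <- bs
  attr(out, "config") <- config
  attr(out, "stage_counts") <- counts
  out
}

#' @export
print.loop_calls <- function(x, ...) {
  cat(sprintf("<loop_calls> %d loops\n", nrow(x)))
  if (nrow(x)) {
    df <- as.data.frame(x)
    print(utils::head(df[, c("chrom", "bin_i", "bin_j", "obs_exp",
                             "raw_count", "p_horizontal", "p_vertical",
                             "p_corner")], 10L))
    if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' @export
summary.loop_calls <- function(object, ...) {
  sc <- attr(object, "stage_counts")
  cat(sprintf("Loop calls: %d accepted\n", nrow(object)))
  if (!is.null(sc)) {
    cat("Candidate counts by filter stage:\n")
    for (k in names(sc)) cat(sprintf("  %-12s %d\n", k, sc[[k]]))
  }
  if (nrow(object))
    cat(sprintf("Anchor distance (bins): %d..%d; obs/exp: %.2f..%.2f\n",
                min(object$bin_j - object$bin_i),
                max(object$bin_j - object$bin_i),
                min(object$obs_exp), max(object$obs_exp)))
  invisible(object)
}
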