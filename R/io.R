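#' Load a balanced Hi-C contact matrix from triplet text
#'
#' Reads a per-chromosome contact matrix stored as whitespace-separated
#' triplet text (`bin_i bin_j count`, 0-based bin indices, `#` comments
#' allowed) with a JSON sidecar `<path>.json` holding the geometry
#' (`chrom`, `bin_size`, `n_bins`) and, optionally, per-bin balancing
#' `weights`. Entries are restricted to genomic distances
#' `min_distance/bin_size <= j - i <= max_distance/bin_size`. When
#' `use_balanced` is `TRUE` the analysis values are `w_i * w_j * count`;
#' raw counts remain available in the `raw` field either way.
#'
#' @param path Path to the triplet text file; `<path>.json` must exist.
#' @param chrom Optional chromosome name; must match the sidecar.
#' @param max_distance,min_distance Band limits in base pairs.
#' @param use_balanced Apply balancing weights (requires weights in the
#'   sidecar).
#' @return A [contact_matrix()].
#' @export
load_contact_matrix <- function(path, chrom = NULL,
                                max_distance = 2e6, min_distance = 0,
                                use_balanced = FALSE) {
  if (!file.exists(path))
    stop_nbloop("io", "matrix file not found: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_nbloop("io", "sidecar not found: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("chrom", "bin_size", "n_bins"))
    if (is.null(meta[[f]]))
      stop_nbloop("io", "sidecar misses field '%s'", f)
  if (!is.null(chrom) && !identical(chrom, meta$chrom))
    stop_nbloop("chrom", "chromosome '%s' not present in %s (has '%s')",
                chrom, path, meta$chrom)
  if (max_distance < min_distance || min_distance < 0)
    stop_nbloop("config", "require max_distance >= min_distance >= 0")
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("bin_i", "bin_j", "count"),
                           colClasses = c("integer", "integer", "numeric"))
  if (nrow(tab) > 0 && (any(!is.finite(tab$count)) || any(tab$count < 0)))
    stop_nbloop("value", "negative or non-finite counts in %s", path)
  value <- tab$count
  balanced <- FALSE
  if (use_balanced) {
    w <- meta$weights
    if (is.null(w))
      stop_nbloop("weights", "balanced values requested but %s stores no weights",
                  sidecar)
    if (length(w) != meta$n_bins)
      stop_nbloop("weights", "weights length != n_bins")
    value <- w[tab$bin_i + 1L] * w[tab$bin_j + 1L] * tab$count
    balanced <- TRUE
  }
  bs <- as.numeric(meta$bin_size)
  contact_matrix(chrom = meta$chrom, bin_size = bs, n_bins = meta$n_bins,
                 i = tab$bin_i, j = tab$bin_j, value = value, raw = tab$count,
                 balanced = balanced,
                 min_band = as.integer(ceiling(min_distance / bs)),
                 max_band = as.integer(floor(max_distance / bs)))
}

#' Write a contact matrix as triplet text with a JSON sidecar
#'
#' @param mat A [contact_matrix()]; raw counts are written.
#' @param path Output path; the sidecar goes to `<path>.json`.
#' @param weights Optional per-bin balancing weights stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(mat, path, weights = NULL) {
  meta <- list(chrom = mat$chrom, bin_size = mat$bin_size,
               n_bins = mat$n_bins)
  if (!is.null(weights)) meta$weights <- weights
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bin_i\tbin_j\tcount", con)
  if (length(mat$i))
    writeLines(sprintf("%d\t%d\t%.15g", mat$i, mat$j, mat$raw), con)
  invisible(path)
}

bedpe_header <- paste0("#chrom1\tstart1\tend1\tchrom2\tstart2\tend2\tname\t",
                       "score\tstrand1\tstrand2\tobs_exp\traw_count\t",
                       "p_preselect\tp_horizontal\tp_vertical\tp_corner")

#' Write loop calls in BEDPE format
#'
#' Columns: the six standard BEDPE anchor fields, `name`, `score` (`.`),
#' both strands (`.`), then the observed/expected value, raw count and the
#' four p-values (preselection plus the three rank-sum tests). Rows are
#' sorted by (chrom, bin_i, bin_j); byte output is deterministic for a
#' fixed loop set.
#'
#' @param loops A `loop_calls` data frame (see [call_loops()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_loops_bedpe <- function(loops, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop_nbloop("io", "cannot write %s", path))
  on.exit(close(con))
  writeLines(bedpe_header, con)
  if (nrow(loops)) {
    ord <- order(loops$chrom, loops$bin_i, loops$bin_j)
    l <- loops[ord, , drop = FALSE]
    writeLines(sprintf(
      "%s\t%d\t%d\t%s\t%d\t%d\tloop_%d\t.\t.\t.\t%.15g\t%.15g\t%.15g\t%.15g\t%.15g\t%.15g",
      l$chrom, l$start1, l$end1, l$chrom, l$start2, l$end2,
      seq_len(nrow(l)), l$obs_exp, l$raw_count, l$p_preselect,
      l$p_horizontal, l$p_vertical, l$p_corner), con)
  }
  invisible(path)
}

#' Read loop calls from BEDPE written by [write_loops_bedpe()]
#'
#' @param path BEDPE file path.
#' @return A `loop_calls` data frame.
#' @export
read_loops_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_loop_calls())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 16L))
    stop_nbloop("io", "malformed BEDPE line (need 16 fields)")
  g <- function(k, num = TRUE) {
    v <- vapply(f, `[[`, "", k)
    if (!num) return(v)
    v[v %in% c(".", "NA", "nan")] <- NA_character_
    as.numeric(v)
  }
  start1 <- g(2); end1 <- g(3); start2 <- g(5); end2 <- g(6)
  bin_size <- end1[1] - start1[1]
  out <- data.frame(
    chrom = g(1, FALSE),
    bin_i = as.integer(start1 / bin_size), bin_j = as.integer(start2 / bin_size),
    start1 = as.integer(start1), end1 = as.integer(end1),
    start2 = as.integer(start2), end2 = as.integer(end2),
    obs_exp = g(11), raw_count = g(12), p_preselect = g(13),
    p_horizontal = g(14), p_vertical = g(15), p_corner = g(16),
    stringsAsFactors = FALSE)
  class(out) <- c("loop_calls", "data.frame")
  out
}

#' Read genomic intervals from BED text
#'
#' Accepts 3+ column BED (0-based, half-open); `track`, `browser`, `#` and
#' empty lines are skipped. An interval with `start >= end` raises an error
#' naming the offending line.
#'
#' @param path BED file path.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @export
read_intervals_bed <- function(path) {
  if (!file.exists(path)) stop_nbloop("io", "BED file not found: %s", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  idx <- which(keep)
  if (!length(idx))
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  f <- strsplit(lines[idx], "[ \t]+")
  if (any(lengths(f) < 3L))
    stop_nbloop("bed", "line %d: fewer than 3 BED columns",
                idx[which(lengths(f) < 3L)[1L]])
  chrom <- vapply(f, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(f, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop_nbloop("bed", "line %d: non-numeric coordinates",
                idx[which(is.na(start) | is.na(end))[1L]])
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop_nbloop("bed", "line %d: start >= end (or negative start)", idx[bad[1L]])
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}
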