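# Shared fixture builders; everything is generated in code, no stored data.

# 4-bin toy matrix from the band-definition examples.
toy4 <- function() {
  contact_matrix(chrom = "chrT", bin_size = 1e4, n_bins = 4,
                 i = c(0L, 1L, 2L, 0L), j = c(1L, 2L, 3L, 3L),
                 value = c(2, 2, 2, 5))
}

# Write a triplet-text matrix (+ sidecar) into a temp dir; returns the path.
write_toy_triplet <- function(dir = NULL, weights = NULL,
                              counts = c(2, 2, 2, 5)) {
  if (is.null(dir)) {
    dir <- tempfile("toyfix")
    dir.create(dir)
  }
  path <- file.path(dir, "toy.tsv")
  meta <- list(chrom = "chrT", bin_size = 1e4, n_bins = 4)
  if (!is.null(weights)) meta$weights <- weights
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  writeLines(c("# test fixture",
               sprintf("%d\t%d\t%g", c(0, 1, 2, 0), c(1, 2, 3, 3), counts)),
             path)
  path
}

# A random banded matrix with positive entries for property-style tests.
random_matrix <- function(seed, n_bins = 40, max_band = 12, p_zero = 0.3) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] <= max_band, , drop = FALSE]
  vals <- stats::rpois(nrow(idx), 6) * stats::rbinom(nrow(idx), 1, 1 - p_zero)
  keep <- vals > 0
  contact_matrix(chrom = "chrR", bin_size = 1e4, n_bins = n_bins,
                 i = idx[keep, 1] - 1L, j = idx[keep, 2] - 1L,
                 value = vals[keep], max_band = max_band)
}

# A fitted-looking distance model with chosen parameters.
fake_model <- function(r, p, d = 5L) {
  structure(list(d = d, r = r, p = p, n_obs = 1000L, fit_ok = TRUE,
                 method = "fixed"), class = "distance_model")
}

# Exact one-sided rank-sum p-value P(W >= w_obs) by full enumeration of all
# choose(n1+n2, n1) rank assignments; requires tie-free pooled values.
ranksum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  n1 <- length(x); n <- length(pooled)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  combs <- utils::combn(n, n1)
  mean(colSums(combs) >= r_obs)
}

# Small planted-loop dataset for pipeline smoke tests (fast to generate
# and call; the full-scale study conditions live in the acceptance tests).
small_planted <- function(seed = 1, n_bins = 1000, n_loops = 9) {
  spec <- synthetic_spec(n_bins = n_bins, max_band = 120, seed = seed,
                         loops = plant_loops(n_bins, n_loops))
  generate_dataset(spec)
}
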