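#' Specification for a synthetic Hi-C contact matrix
#'
#' Defines a seeded generator of per-chromosome contact matrices with
#' power-law distance decay, per-distance negative binomial dispersion and
#' optionally planted loop enrichments, sparsity and faulty (zeroed)
#' regions. The expected count at distance `d` bins is
#' `decay_scale * max(d, 1)^(-decay_alpha) + decay_floor`; counts are drawn
#' from a negative binomial with that mean and variance
#' `dispersion * mean`. Loops multiply the mean in a
#' `(2*spread+1)^2` patch by a radially tapering kernel peaking at the
#' loop's enrichment factor, so the planted obs/exp enrichment is
#' scale-free.
#'
#' The defaults emulate a moderately sequenced 10-kb intra-chromosomal
#' matrix in the sparse-count regime (per-pixel means of order 1 in the
#' loop-distance range), where per-distance overdispersion holds and
#' negative binomial modelling is well posed.
#'
#' @param n_bins Number of bins of the chromosome.
#' @param bin_size Bin size in base pairs.
#' @param max_band Maximum generated distance in bins.
#' @param decay_scale,decay_alpha,decay_floor Distance-decay parameters.
#' @param dispersion Variance/mean ratio of the counts; must exceed 1
#'   (the negative binomial requires overdispersion).
#' @param loops Data frame with columns `i`, `j`, `enrichment`, `spread`
#'   (see [plant_loops()]), or `NULL` for a null matrix.
#' @param sparsity Fraction of generated entries zeroed at random.
#' @param faulty_regions List of bin ranges `c(from, to)` whose rows and
#'   columns are zeroed (emulating unmappable regions).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_bins = 2000, bin_size = 1e4, max_band = 200,
                           decay_scale = 8192, decay_alpha = 2.5,
                           decay_floor = 0.02, dispersion = 3,
                           loops = NULL, sparsity = 0,
                           faulty_regions = NULL, seed = 1L) {
  if (dispersion <= 1)
    stop_nbloop("dispersion", "dispersion must exceed 1 (NB overdispersion)")
  if (sparsity < 0 || sparsity >= 1)
    stop_nbloop("config", "sparsity must lie in [0, 1)")
  if (!is.null(loops)) {
    stopifnot(all(c("i", "j", "enrichment", "spread") %in% names(loops)))
    if (any(loops$enrichment <= 1))
      stop_nbloop("config", "loop enrichment factors must exceed 1")
    if (any(loops$i >= loops$j) ||
        any(loops$j - loops$i > max_band) ||
        any(loops$i < 0) || any(loops$j >= n_bins))
      stop_nbloop("config", "loop centers must lie inside the band")
  }
  structure(list(n_bins = as.integer(n_bins), bin_size = bin_size,
                 max_band = as.integer(max_band),
                 decay_scale = decay_scale, decay_alpha = decay_alpha,
                 decay_floor = decay_floor, dispersion = dispersion,
                 loops = loops, sparsity = sparsity,
                 faulty_regions = faulty_regions,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Deterministically place loops along a synthetic chromosome
#'
#' Spreads `n_loops` loop centers evenly along the diagonal, cycling the
#' anchor distance through the small set `d_set` (loop sizes in real data
#' cluster around recurrent characteristic distances, and several loops
#' per distance stabilizes the per-distance fit); placement involves no
#' randomness, so a truth set is fully determined by its arguments.
#'
#' @param n_bins Chromosome size in bins.
#' @param n_loops Number of loops.
#' @param d_set Anchor distances in bins, cycled across loops.
#' @param enrichment Peak mean multiplier at the loop center.
#' @param spread Kernel inradius in bins (patch is `(2*spread+1)^2`).
#' @param margin Keep centers this many bins away from the matrix edge.
#' @return A data frame with columns `i`, `j`, `enrichment`, `spread`.
#' @export
plant_loops <- function(n_bins, n_loops = 20, d_set = c(16, 17, 18),
                        enrichment = 8, spread = 5, margin = 30) {
  ds <- rep_len(d_set, n_loops)
  is <- round(seq(margin, n_bins - margin - max(ds), length.out = n_loops))
  data.frame(i = as.integer(is), j = as.integer(is + ds),
             enrichment = enrichment, spread = as.integer(spread))
}

# Mean decay at distance d (bins).
decay_mean <- function(spec, d) {
  spec$decay_scale * pmax(d, 1)^(-spec$decay_alpha) + spec$decay_floor
}

# Radial kernel of the loop enrichment: multiplier at Chebyshev ring rho
# of a loop with peak enrichment E and inradius `spread`: a flat core at
# the full factor up to one bin from the center, then an exponentially
# decaying shoulder (25% of the excess two bins out, roughly halving per
# further bin). A sharp peak with an enriched direct neighborhood, the
# shape aggregate loop pileups show at 10 kb resolution.
loop_multiplier <- function(E, rho, spread) {
  w <- ifelse(rho <= 1, 1, 0.25 * exp(-(rho - 2) / 1.4))
  1 + (E - 1) * w
}

#' Generate a synthetic contact matrix with known truth
#'
#' Draws counts per band entry from a negative binomial with the spec's
#' distance-decay mean (times the planted loop enrichment kernel where
#' applicable) and variance `dispersion * mean`. Deterministic given
#' `spec$seed`: the same spec yields byte-identical matrices. Zero counts
#' are not stored (sparse semantics).
#'
#' @param spec A [synthetic_spec()].
#' @param chrom Chromosome name for the generated matrix.
#' @return A list with elements `matrix` (a [contact_matrix()]), `truth`
#'   (data frame of planted loop centers `i`, `j`) and `spec`.
#' @export
generate_dataset <- function(spec, chrom = "chrS") {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_bins
  # per-entry loop multipliers, folded to the upper triangle; overlapping
  # kernels keep the larger multiplier
  la <- integer(0); lb <- integer(0); lm <- numeric(0)
  if (!is.null(spec$loops)) {
    for (k in seq_len(nrow(spec$loops))) {
      lp <- spec$loops[k, ]
      off <- expand.grid(da = -lp$spread:lp$spread, db = -lp$spread:lp$spread)
      a <- lp$i + off$da; b <- lp$j + off$db
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
      ok <- a >= 0 & b < n & (b - a) <= spec$max_band
      la <- c(la, a[ok]); lb <- c(lb, b[ok])
      lm <- c(lm, loop_multiplier(lp$enrichment,
                                  pmax(abs(off$da), abs(off$db))[ok],
                                  lp$spread))
    }
    key <- paste(la, lb)
    best <- tapply(lm, key, max)
    first <- !duplicated(key)
    la <- la[first]; lb <- lb[first]
    lm <- as.numeric(best[paste(la, lb)])
  }
  ld <- lb - la
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (d in 0:spec$max_band) {
    n_el <- n - d
    if (n_el <= 0) break
    mu <- rep(decay_mean(spec, d), n_el)
    a_idx <- 0:(n_el - 1L)
    sel <- which(ld == d)
    if (length(sel)) mu[la[sel] + 1L] <- mu[la[sel] + 1L] * lm[sel]
    size <- mu / (spec$dispersion - 1)
    counts <- stats::rnbinom(n_el, mu = mu, size = size)
    if (spec$sparsity > 0)
      counts[stats::runif(n_el) < spec$sparsity] <- 0L
    nz <- counts > 0
    ii <- c(ii, a_idx[nz]); jj <- c(jj, a_idx[nz] + d)
    vv <- c(vv, counts[nz])
  }
  if (!is.null(spec$faulty_regions)) {
    for (rg in spec$faulty_regions) {
      hit <- (ii >= rg[1L] & ii <= rg[2L]) | (jj >= rg[1L] & jj <= rg[2L])
      ii <- ii[!hit]; jj <- jj[!hit]; vv <- vv[!hit]
    }
  }
  mat <- contact_matrix(chrom = chrom, bin_size = spec$bin_size, n_bins = n,
                        i = ii, j = jj, value = vv, raw = vv,
                        balanced = FALSE, min_band = 0L,
                        max_band = spec$max_band)
  truth <- if (is.null(spec$loops))
    data.frame(i = integer(0), j = integer(0))
  else spec$loops[, c("i", "j")]
  list(matrix = mat, truth = truth, spec = spec)
}

# Greedy one-to-one matching of two loop sets within Chebyshev tolerance,
# in genomic position order. Returns indices of matched pairs.
greedy_match <- function(ai, aj, bi, bj, tol_bins) {
  used_b <- rep(FALSE, length(bi))
  ma <- integer(0); mb <- integer(0)
  ord_a <- order(ai, aj)
  for (k in ord_a) {
    cheb <- pmax(abs(ai[k] - bi), abs(aj[k] - bj))
    cand <- which(!used_b & cheb <= tol_bins)
    if (length(cand)) {
      pick <- cand[which.min(cheb[cand])]
      used_b[pick] <- TRUE
      ma <- c(ma, k); mb <- c(mb, pick)
    }
  }
  list(a = ma, b = mb)
}

#' Score called loops against a planted truth set
#'
#' Greedy one-to-one matching within a Chebyshev bin tolerance. Precision
#' is `matched / called` (reported as 1 with zero matches when nothing was
#' called, by convention) and recall `matched / truth` (1 when the truth
#' set is empty).
#'
#' @param called A `loop_calls` data frame (or any frame with
#'   `bin_i`/`bin_j` or `i`/`j` columns).
#' @param truth Data frame of planted centers (`i`, `j`).
#' @param tol_bins Chebyshev matching tolerance in bins.
#' @return A list with `precision`, `recall`, `n_matched` and the matched
#'   index pairs.
#' @export
score_recovery <- function(called, truth, tol_bins = 2) {
  ci <- called$bin_i %||% called$i
  cj <- called$bin_j %||% called$j
  m <- greedy_match(truth$i, truth$j, ci, cj, tol_bins)
  n_match <- length(m$a)
  list(precision = if (length(ci) == 0) 1 else n_match / length(ci),
       recall = if (nrow(truth) == 0) 1 else n_match / nrow(truth),
       n_matched = n_match,
       matched = data.frame(truth_idx = m$a, called_idx = m$b))
}
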