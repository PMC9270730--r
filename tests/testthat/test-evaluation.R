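loops_df <- function(chrom, bi, bj, bs = 1e4) {
  out <- data.frame(chrom = chrom, bin_i = bi, bin_j = bj,
                    start1 = as.integer(bi * bs),
                    end1 = as.integer((bi + 1) * bs),
                    start2 = as.integer(bj * bs),
                    end2 = as.integer((bj + 1) * bs))
  class(out) <- c("loop_calls", "data.frame")
  out
}

test_that("anchor matching requires peaks at both loci", {
  loops <- loops_df("chr1", 10, 30)
  both <- data.frame(chrom = "chr1", start = c(105000L, 305000L),
                     end = c(105200L, 305200L))
  expect_equal(anchors_match_intervals(loops, both, 1e4)$fraction, 1)
  one <- both[1, ]
  expect_equal(anchors_match_intervals(loops, one, 1e4)$n_matched, 0L)
  none <- both[0, ]
  expect_equal(anchors_match_intervals(loops, none, 1e4)$fraction, 0)
})

test_that("peaks spanning bin borders cover every touched bin", {
  loops <- loops_df("chr1", c(10, 11), c(30, 40))
  spanning <- data.frame(chrom = "chr1", start = 109990L, end = 110020L)
  far <- data.frame(chrom = "chr1", start = c(305000L, 405000L),
                    end = c(305100L, 405100L))
  rep <- anchors_match_intervals(loops, rbind(spanning, far), 1e4)
  expect_equal(rep$n_matched, 2L)  # the spanning peak hits bins 10 and 11
})

test_that("chromosome mismatches warn and count as unmatched", {
  loops <- loops_df(c("chr1", "chr2"), c(10, 10), c(30, 30))
  peaks <- data.frame(chrom = "chr1", start = c(105000L, 305000L),
                      end = c(105100L, 305100L))
  expect_warning(rep <- anchors_match_intervals(loops, peaks, 1e4), "chr2")
  expect_equal(rep$n_matched, 1L)
})

test_that("adding peaks never decreases the matched fraction", {
  set.seed(21)
  loops <- loops_df("chr1", sample(0:200, 15), 300 + sample(0:200, 15))
  pk <- data.frame(chrom = "chr1",
                   start = as.integer(sort(sample(0:5e6, 60)) %/% 100 * 100))
  pk$end <- pk$start + 500L
  prev <- 0
  for (n in c(5, 20, 40, 60)) {
    f <- anchors_match_intervals(loops, pk[seq_len(n), ], 1e4)$fraction
    expect_gte(f, prev)
    prev <- f
  }
})

test_that("loop-set intersection obeys identity and boundary tolerance", {
  a <- data.frame(i = c(10, 50, 90), j = c(40, 90, 140))
  expect_equal(intersect_loop_sets(a, a, 0)$n_intersect, 3L)
  far <- data.frame(i = a$i + 500, j = a$j + 500)
  expect_equal(intersect_loop_sets(a, far, 0)$n_intersect, 0L)
  shifted <- data.frame(i = a$i + 3, j = a$j + 3)
  expect_equal(intersect_loop_sets(a, shifted, 3)$n_intersect, 3L)
  expect_equal(intersect_loop_sets(a, shifted, 2)$n_intersect, 0L)
  # matched count is symmetric and bounded
  b <- data.frame(i = c(10, 11), j = c(40, 40))
  ab <- intersect_loop_sets(a, b, 1)
  ba <- intersect_loop_sets(b, a, 1)
  expect_equal(ab$n_intersect, ba$n_intersect)
  expect_lte(ab$n_intersect, min(ab$n_a, ab$n_b))
})

test_that("two-proportion z-test matches the pooled closed form", {
  eq <- proportion_z_test(50, 100, 50, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_two_sided, 1)
  got <- proportion_z_test(50, 100, 30, 100)
  phat <- 80 / 200
  ref_z <- (0.5 - 0.3) / sqrt(phat * (1 - phat) * (1 / 100 + 1 / 100))
  expect_equal(got$z, ref_z, tolerance = 1e-12)
  # cross-check against the chi-squared equivalence (z^2 = X^2)
  chi <- suppressWarnings(prop.test(c(50, 30), c(100, 100),
                                    correct = FALSE))
  expect_equal(got$z^2, unname(chi$statistic), tolerance = 1e-10)
  expect_equal(got$p_two_sided, chi$p.value, tolerance = 1e-10)
  swapped <- proportion_z_test(30, 100, 50, 100)
  expect_equal(swapped$z, -got$z)
  expect_equal(swapped$p_two_sided, got$p_two_sided)
  # degenerate pooled proportions use the documented convention
  expect_equal(proportion_z_test(0, 50, 0, 80), list(z = 0, p_two_sided = 1))
  expect_equal(proportion_z_test(50, 50, 80, 80), list(z = 0, p_two_sided = 1))
  expect_error(proportion_z_test(5, 0, 1, 10), class = "nbloop_domain_error")
  expect_error(proportion_z_test(11, 10, 1, 10), class = "nbloop_domain_error")
})

test_that("aggregate pileup averages submatrices and skips clipped loops", {
  m <- random_matrix(14, n_bins = 60, max_band = 40)
  oe <- transform_obs_exp(m, compute_expected(m, "all"))
  one <- data.frame(bin_i = 20, bin_j = 40)
  agg1 <- aggregate_loop_submatrices(oe, one, half_width = 3)
  lk <- nbloop:::symmetric_lookup(oe)
  direct <- matrix(lk[cbind(rep(17:23, each = 7) + 1, rep(37:43, 7) + 1)],
                   7, byrow = TRUE)
  expect_equal(unclass(agg1), direct, ignore_attr = TRUE)
  # two identical loops: mean equals the shared submatrix
  two <- data.frame(bin_i = c(20, 20), bin_j = c(40, 40))
  agg2 <- aggregate_loop_submatrices(oe, two, half_width = 3)
  expect_equal(unclass(agg2), direct, ignore_attr = TRUE)
  expect_equal(attr(agg2, "n_used"), 2L)
  # a loop whose window exits the band is skipped and counted
  mixed <- data.frame(bin_i = c(20, 1), bin_j = c(40, 39))
  agg3 <- aggregate_loop_submatrices(oe, mixed, half_width = 3)
  expect_equal(attr(agg3, "n_skipped"), 1L)
  expect_error(aggregate_loop_submatrices(oe, one[0, ], 3),
               class = "nbloop_no_loops_error")
  expect_error(aggregate_loop_submatrices(oe, data.frame(bin_i = 1,
                                                         bin_j = 39), 3),
               class = "nbloop_no_loops_error")
})

test_that("the pileup of planted loops peaks at its center", {
  ds <- generate_dataset(synthetic_spec(seed = 3,
                                        loops = plant_loops(2000)))
  mat <- nbloop:::restrict_band(ds$matrix, 4L, 200L)
  oe <- transform_obs_exp(mat, compute_expected(mat, "all"))
  agg <- aggregate_loop_submatrices(oe, ds$truth, half_width = 5)
  # the maximum sits inside the flat 3x3 loop core, centered on the call
  peak_pos <- which(agg == max(agg), arr.ind = TRUE)
  expect_true(all(abs(peak_pos - 6) <= 1))
  center <- agg[6, 6]
  expect_gte(center, max(agg[abs(row(agg) - 6) > 1 | abs(col(agg) - 6) > 1]))
  expect_gt(center / mean(agg), 2)
})
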