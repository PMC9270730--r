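cand_df <- function(i, j, obs_exp, raw = 20, p = 0.01) {
  data.frame(i = i, j = j, d = j - i, obs_exp = obs_exp, raw = raw,
             p_preselect = p)
}

test_that("pooling keeps the highest obs/exp candidate per neighborhood", {
  x <- cand_df(c(10, 11), c(20, 21), c(2.0, 3.0))
  out <- pool_candidates(x, window_size = 5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$i, 11)
  # far-apart candidates both survive
  y <- cand_df(c(10, 30), c(20, 40), c(2.0, 3.0))
  expect_equal(nrow(pool_candidates(y, 5)), 2L)
})

test_that("pooling ties break by smaller distance then smaller i", {
  x <- cand_df(c(10, 11), c(20, 21), c(3.0, 3.0))
  out <- pool_candidates(x, 5)
  expect_equal(out$i, 10)
  z <- cand_df(c(11, 10), c(20, 21), c(3.0, 3.0))  # d = 9 vs 11
  expect_equal(pool_candidates(z, 5)$i, 11)
})

test_that("pooling is idempotent and enforces the separation invariant", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 60
    x <- cand_df(sample(0:80, n, TRUE), 100 + sample(0:80, n, TRUE),
                 runif(n, 1.5, 9))
    x <- x[!duplicated(paste(x$i, x$j)), ]
    p1 <- pool_candidates(x, 5)
    p2 <- pool_candidates(p1, 5)
    expect_equal(p1[, c("i", "j", "obs_exp")], p2[, c("i", "j", "obs_exp")])
    if (nrow(p1) > 1) {
      dd <- as.matrix(dist(cbind(p1$i, p1$j), method = "maximum"))
      expect_true(all(dd[upper.tri(dd)] > 5))
    }
    # every absorbed candidate is dominated by some surviving neighbor
    for (k in seq_len(nrow(x))) {
      if (any(p1$i == x$i[k] & p1$j == x$j[k])) next
      near <- pmax(abs(p1$i - x$i[k]), abs(p1$j - x$j[k])) <= 5
      expect_gte(max(p1$obs_exp[near]) + 1e-12, x$obs_exp[k])
    }
  }
})

test_that("interior neighborhoods have the exact region geometry", {
  m <- random_matrix(2, n_bins = 80, max_band = 60)
  oe <- transform_obs_exp(m, compute_expected(m, "all"))
  nb <- extract_neighborhood(oe, c(30, 60), peak_width = 2, window_size = 5)
  expect_equal(nb$n_window, 121L)          # (2*5+1)^2
  expect_length(nb$peak, 25L)              # (2*2+1)^2
  expect_length(nb$all_background, 96L)
  expect_length(nb$horizontal, 30L)
  expect_length(nb$vertical, 30L)
  expect_length(nb$corner, 9L)
  # 4 unclassified window corners of 3x3 minus the bottom-left one
  expect_equal(121L - 25L - 30L - 30L - 9L, 27L)
  expect_true(nb$testable)
})

test_that("window truncation matches brute-force enumeration of valid cells", {
  m <- random_matrix(6, n_bins = 50, max_band = 20)
  oe <- transform_obs_exp(m, compute_expected(m, "all"))
  for (center in list(c(2, 10), c(40, 47), c(30, 49), c(10, 14))) {
    nb <- extract_neighborhood(oe, center, 2, 5)
    count <- 0L
    for (da in -5:5) for (db in -5:5) {
      a <- center[1] + da; b <- center[2] + db
      d <- abs(b - a)
      if (a >= 0 && b >= 0 && a < 50 && b < 50 &&
          d >= oe$min_band && d <= oe$max_band)
        count <- count + 1L
    }
    expect_equal(nb$n_window, count)
  }
})

test_that("unstored in-band cells read as zeros inside the window", {
  m <- contact_matrix("c", 1e4, 40, i = 20, j = 30, value = 4,
                      min_band = 0L, max_band = 20L)
  class(m) <- c("obs_exp_matrix", "contact_matrix")
  nb <- extract_neighborhood(m, c(20, 30), 2, 5)
  expect_equal(sum(nb$peak > 0), 1L)
  expect_equal(sum(nb$all_background), 0)
  expect_equal(nb$n_window, 121L)
})

test_that("the mean filter rejects before any testing", {
  nb <- structure(list(center = c(5, 15), peak = rep(1, 25),
                       horizontal = rep(2, 30), vertical = rep(2, 30),
                       corner = rep(2, 9), all_background = rep(2, 96),
                       n_window = 121L, testable = TRUE),
                  class = "neighborhood")
  ev <- evaluate_neighborhood(nb, 0.025)
  expect_false(ev$accepted)
  expect_identical(ev$reason, "mean_filter")
  expect_true(is.na(ev$p_horizontal))
})

test_that("rank-sum p-values match exact enumeration (1/84 example)", {
  p <- nbloop:::rank_sum_p(c(10, 11, 12), 1:6)
  expect_equal(p, 1 / 84, tolerance = 1e-12)
  expect_equal(ranksum_enum_p(c(10, 11, 12), 1:6), 1 / 84, tolerance = 1e-12)
})

test_that("rank-sum agrees with enumeration for all group sizes up to 8", {
  set.seed(99)
  for (n1 in c(2, 3, 5, 8)) {
    for (n2 in c(2, 4, 6, 8)) {
      for (rep in 1:3) {
        pooled <- sample(seq_len(50), n1 + n2)
        x <- pooled[seq_len(n1)]; y <- pooled[-seq_len(n1)]
        expect_equal(nbloop:::rank_sum_p(x, y), ranksum_enum_p(x, y),
                     tolerance = 1e-12,
                     label = sprintf("n1=%d n2=%d", n1, n2))
      }
    }
  }
})

test_that("identical distributions in all regions are never accepted", {
  nb <- structure(list(center = c(5, 15), peak = rep(3, 25),
                       horizontal = rep(3, 30), vertical = rep(3, 30),
                       corner = rep(3, 9), all_background = rep(3, 96),
                       n_window = 121L, testable = TRUE),
                  class = "neighborhood")
  ev <- evaluate_neighborhood(nb, 0.025)
  expect_false(ev$accepted)
})

test_that("untestable neighborhoods are rejected with a reason", {
  nb <- structure(list(center = c(1, 3), peak = 1:4, horizontal = numeric(0),
                       vertical = 1:3, corner = 1:2, all_background = 1:9,
                       n_window = 18L, testable = FALSE,
                       reason = "empty_region"),
                  class = "neighborhood")
  ev <- evaluate_neighborhood(nb, 0.025)
  expect_false(ev$accepted)
  expect_identical(ev$reason, "empty_region")
})

test_that("call_loops handles empty and unfittable matrices gracefully", {
  empty <- contact_matrix("c", 1e4, 100, i = integer(0), j = integer(0),
                          value = numeric(0))
  out <- suppressWarnings(call_loops(empty))
  expect_s3_class(out, "loop_calls")
  expect_equal(nrow(out), 0L)
  sparse <- contact_matrix("c", 1e4, 100, i = c(0, 10), j = c(20, 40),
                           value = c(3, 5))
  w <- capture_warnings(out2 <- call_loops(sparse))
  expect_true(any(grepl("no fittable", w)))
  expect_equal(nrow(out2), 0L)
})

test_that("the pipeline recovers planted loops on a small chromosome", {
  ds <- small_planted(seed = 2)
  calls <- suppressWarnings(call_loops(ds$matrix,
                                       loop_config(expected_mode = "all")))
  sc <- score_recovery(calls, ds$truth, tol_bins = 2)
  expect_gte(sc$recall, 0.5)
  expect_gte(sc$precision, 0.8)
  # output sorted by anchors, p-values within the configured level
  expect_true(!is.unsorted(calls$bin_i))
  expect_true(all(calls$p_horizontal < 0.025))
  expect_true(all(calls$p_vertical < 0.025))
  expect_true(all(calls$p_corner < 0.025))
  # accepted loops beat the mean filter by construction
  counts <- attr(calls, "stage_counts")
  expect_true(all(diff(counts) <= 0))
})
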