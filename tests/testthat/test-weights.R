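test_that("Fisher p-values match exhaustive hypergeometric enumeration", {
  set.seed(42)
  for (rep in 1:40) {
    n_set <- sample(2:10, 1)
    n_rest <- sample(5:20, 1)
    n_bits <- 8
    set_fp <- matrix(rbits(n_set * n_bits, 0.4), n_set, n_bits)
    rest_fp <- matrix(rbits(n_rest * n_bits, 0.2), n_rest, n_bits)
    p <- binary_feature_pvalues(set_fp, rest_fp)
    for (j in seq_len(n_bits)) {
      expected <- oracle_fisher_one_sided(
        sum(set_fp[, j]), n_set, sum(rest_fp[, j]), n_rest
      )
      expect_equal(p[[j]], expected, tolerance = 1e-12)
    }
  }
})

test_that("Fisher p-values agree with fisher.test and handle set-in-background", {
  # 5-ligand set all carrying a bit found nowhere else in a 100-ligand library
  set_fp <- matrix(1L, 5, 1)
  bg_fp <- matrix(c(rep(1L, 5), rep(0L, 95)), ncol = 1)
  p <- binary_feature_pvalues(set_fp, bg_fp, set_rows = 1:5)
  expect_equal(p[[1]], 1 / choose(100, 5), tolerance = 1e-12)
  # cross-check a composite table against fisher.test
  ft <- stats::fisher.test(
    matrix(c(4, 1, 6, 19), 2, byrow = TRUE),
    alternative = "greater"
  )
  set_fp <- matrix(c(rep(1L, 4), 0L), ncol = 1)
  rest_fp <- matrix(c(rep(1L, 6), rep(0L, 19)), ncol = 1)
  expect_equal(
    binary_feature_pvalues(set_fp, rest_fp)[[1]], ft$p.value,
    tolerance = 1e-12
  )
})

test_that("Fisher degenerate cases follow the stated conventions", {
  expect_error(binary_feature_pvalues(matrix(0L, 0, 4), matrix(0L, 5, 4)))
  # bit absent everywhere -> p = 1 and flagged
  p <- binary_feature_pvalues(matrix(0L, 3, 2), matrix(0L, 10, 2))
  expect_equal(as.numeric(p), c(1, 1))
  expect_equal(attr(p, "flat_bits"), 1:2)
  # equal frequency in set and rest -> no over-representation
  set_fp <- matrix(c(1L, 0L), ncol = 1)
  rest_fp <- matrix(c(1L, 0L, 1L, 0L), ncol = 1)
  expect_gte(binary_feature_pvalues(set_fp, rest_fp)[[1]], 0.5)
})

test_that("rank-sum p-values match complete permutation enumeration", {
  set.seed(99)
  for (rep in 1:15) {
    m <- sample(2:6, 1)
    n <- sample(3:8, 1)
    x <- matrix(stats::rnorm(m), ncol = 1)
    y <- matrix(stats::rnorm(n), ncol = 1)
    p <- continuous_feature_pvalues(x, y)
    expect_equal(p[[1]], oracle_ranksum_exact(x[, 1], y[, 1]),
      tolerance = 1e-12
    )
  }
  # complete separation of {10,11,12} vs {0,1,2}: doubled 1/C(6,3) tail
  p <- continuous_feature_pvalues(
    matrix(c(10, 11, 12), ncol = 1), matrix(c(0, 1, 2), ncol = 1)
  )
  expect_equal(p[[1]], 2 / choose(6, 3), tolerance = 1e-12)
})

test_that("rank-sum approximation path matches wilcox.test on large samples", {
  set.seed(7)
  x <- matrix(stats::rnorm(40, mean = 0.5), ncol = 1)
  y <- matrix(stats::rnorm(120), ncol = 1)
  p <- continuous_feature_pvalues(x, y, exact_max = 10L)
  ref <- stats::wilcox.test(x[, 1], y[, 1], exact = FALSE, correct = TRUE)
  expect_equal(p[[1]], ref$p.value, tolerance = 1e-10)
  # and with ties present
  xt <- matrix(sample(1:5, 30, replace = TRUE), ncol = 1)
  yt <- matrix(sample(2:6, 50, replace = TRUE), ncol = 1)
  pt <- continuous_feature_pvalues(xt, yt, exact_max = 10L)
  reft <- stats::wilcox.test(xt[, 1], yt[, 1], exact = FALSE, correct = TRUE)
  expect_equal(pt[[1]], reft$p.value, tolerance = 1e-10)
})

test_that("rank-sum degenerate cases: identical pooled values and n = 1", {
  p <- continuous_feature_pvalues(
    matrix(rep(2, 3), ncol = 1), matrix(rep(2, 5), ncol = 1)
  )
  expect_equal(p[[1]], 1)
  expect_equal(attr(p, "flat_features"), 1L)
  expect_warning(
    p1 <- continuous_feature_pvalues(
      matrix(5, 1, 1), matrix(stats::rnorm(6), ncol = 1)
    ),
    "low power"
  )
  expect_true(p1[[1]] > 0 && p1[[1]] <= 1)
})

test_that("fast library-stats paths equal the reference p-value functions", {
  set.seed(123)
  n <- 60
  fp <- matrix(rbits(n * 32, 0.15), n, 32)
  desc <- matrix(stats::rnorm(n * 12), n, 12)
  desc[, 3] <- round(desc[, 3]) # introduce ties
  st <- library_feature_stats(fp, desc)
  set_rows <- sample(n, 9)
  expect_equal(
    as.numeric(fast_binary_pvalues(st, fp, set_rows)),
    as.numeric(binary_feature_pvalues(
      fp[set_rows, , drop = FALSE], fp, set_rows
    )),
    tolerance = 1e-12
  )
  expect_equal(
    as.numeric(fast_continuous_pvalues(st, set_rows)),
    as.numeric(continuous_feature_pvalues(
      desc[set_rows, , drop = FALSE], desc, set_rows,
      exact_max = 0L
    )),
    tolerance = 1e-12
  )
})

test_that("BH adjustment matches the direct definition", {
  set.seed(5)
  for (rep in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(adjust_pvalues(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_pvalues(0.3), 0.3)
})

test_that("weights are zero at the threshold and decreasing in q below it", {
  q <- c(0.001, 0.01, 0.049, 0.05, 0.2, 1)
  w <- compute_weights(q, q_threshold = 0.05)
  expect_equal(w[4:6], rep(0, 3))
  expect_true(all(diff(w[1:3]) < 0))
  expect_true(all(w >= 0))
  expect_equal(w[2], 2) # -log10(0.01)
  expect_warning(compute_weights(c(0.5, 0.9)), "all weights zero")
})

test_that("feature selection takes top weights with index tie-breaking", {
  expect_equal(select_features(c(0, 3, 1, 3), 2), c(2L, 4L))
  expect_equal(select_features(c(2, 2, 2), 2), c(1L, 2L))
  expect_equal(select_features(c(1, 2, 3), 3), 1:3)
  expect_warning(sel <- select_features(c(0, 1, 0), 2), "only 1")
  expect_equal(sel, 2L)
  expect_warning(sel0 <- select_features(c(0, 0), 1), "all weights are zero")
  expect_equal(sel0, integer(0))
})

test_that("feature-count optimization maximizes the objective, smallest on ties", {
  expect_equal(optimize_feature_count(c(8, 4, 16), function(m) 1)$m, 4L)
  expect_equal(optimize_feature_count(10, function(m) m)$m, 10L)
  res <- optimize_feature_count(c(2, 4, 8), function(m) -(m - 4)^2)
  expect_equal(res$m, 4L)
  expect_equal(res$objective, 0)
  expect_error(
    optimize_feature_count(c(1, 2), function(m) stop("boom")),
    "every candidate"
  )
})

test_that("feature-count optimization finds the planted signature scale", {
  # moderate-signal ensemble: every signature bit adds retrieval power,
  # extra noise bits dilute the weighted similarity
  b <- tiny_benchmark(seed = 3, p_on = 0.45, n_signature_bits = 12)
  st <- library_feature_stats(b$fp, NULL)
  p <- names(b$sets)[1]
  set_rows <- match(b$sets[[p]], rownames(b$fp))
  pv <- fast_binary_pvalues(st, b$fp, set_rows)
  w_full <- compute_weights(adjust_pvalues(pv), q_threshold = 0.5)
  # objective: AUC of members (LOO max-sim) vs background at feature count m
  others <- setdiff(rownames(b$fp), b$sets[[p]])[1:40]
  obj <- function(m) {
    sel <- suppressWarnings(select_features(w_full, m))
    score_of <- function(id, drop_self) {
      members <- setdiff(b$sets[[p]], if (drop_self) id else NULL)
      s <- ensemble_similarities(
        b$fp[id, ], b$fp[members, , drop = FALSE], w_full, sel, "binary"
      )
      mean(s)
    }
    scores <- c(
      vapply(b$sets[[p]], score_of, numeric(1), drop_self = TRUE),
      vapply(others, score_of, numeric(1), drop_self = FALSE)
    )
    roc_auc(scores, c(
      rep(1, length(b$sets[[p]])),
      rep(0, length(others))
    ))
  }
  res <- optimize_feature_count(c(3, 6, 12, 24, 48, 96), obj)
  s <- b$config$n_signature_bits
  expect_gte(res$m, s / 2)
  expect_lte(res$m, 2 * s)
  expect_gte(res$objective, obj(96))
})

test_that("planted signature features dominate the ensemble weight ranking", {
  b <- tiny_benchmark(seed = 11)
  st <- library_feature_stats(b$fp, b$desc)
  rr <- vapply(names(b$sets), function(p) {
    rows <- match(b$sets[[p]], rownames(b$fp))
    ww <- weight_ensemble(b$fp, b$desc, rows, stats = st)
    rk <- rank(-ww$binary$weights, ties.method = "min")
    1 / min(rk[b$signatures[[p]]$bits])
  }, numeric(1))
  expect_gte(mean(rr), 0.8)
})
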