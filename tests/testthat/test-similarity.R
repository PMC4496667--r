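test_that("weighted Tanimoto matches bitwise enumeration on random pairs", {
  set.seed(1)
  for (rep in 1:200) {
    n <- sample(4:64, 1)
    a <- rbits(n, 0.4)
    b <- rbits(n, 0.4)
    w <- stats::runif(n, 0, 3)
    idx <- sort(sample(n, sample(seq_len(n), 1)))
    expect_identical(
      as.numeric(weighted_tanimoto(a, b, w, idx)),
      oracle_weighted_tanimoto(a, b, w, idx)
    )
  }
})

test_that("weighted Tanimoto hand examples and conventions", {
  expect_equal(
    weighted_tanimoto(c(1, 1, 0, 1), c(1, 0, 1, 1), c(2, 1, 1, 1)), 0.6
  )
  a <- rbits(20, 0.5)
  expect_equal(as.numeric(weighted_tanimoto(a, a, runif(20, 0.1, 1))),
    1,
    tolerance = 1e-15
  )
  expect_equal(
    as.numeric(weighted_tanimoto(
      c(1, 1, 0, 0), c(0, 0, 1, 1), rep(1, 4)
    )), 0
  )
  s <- weighted_tanimoto(c(0, 0), c(0, 0), c(1, 1))
  expect_equal(as.numeric(s), 0)
  expect_true(isTRUE(attr(s, "empty_support")))
})

test_that("weighted Tanimoto reduces to classic Tanimoto for equal weights", {
  set.seed(2)
  for (rep in 1:100) {
    a <- rbits(32, 0.3)
    b <- rbits(32, 0.3)
    if (sum(a | b) == 0) next
    classic <- sum(a & b) / sum(a | b)
    expect_identical(
      as.numeric(weighted_tanimoto(a, b, rep(2.5, 32))), classic
    )
  }
})

test_that("both similarities are symmetric and weight-scale invariant", {
  set.seed(3)
  for (rep in 1:30) {
    n <- 24
    a <- rbits(n, 0.4)
    b <- rbits(n, 0.4)
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    w <- stats::runif(n, 0.1, 2)
    expect_equal(
      as.numeric(weighted_tanimoto(a, b, w)),
      as.numeric(weighted_tanimoto(b, a, w))
    )
    expect_equal(
      as.numeric(weighted_tanimoto(a, b, w * 7)),
      as.numeric(weighted_tanimoto(a, b, w)),
      tolerance = 1e-12
    )
    expect_equal(
      as.numeric(weighted_cosine(x, y, w)),
      as.numeric(weighted_cosine(y, x, w))
    )
  }
})

test_that("weighted cosine hand examples, clipping and zero-norm convention", {
  expect_equal(weighted_cosine(c(1, 0), c(1, 1), c(1, 1)), 1 / sqrt(2),
    tolerance = 1e-12
  )
  x <- stats::rnorm(10)
  expect_equal(as.numeric(weighted_cosine(x, 3 * x, runif(10, 0.5, 2))), 1,
    tolerance = 1e-12
  )
  expect_equal(weighted_cosine(c(1, 0), c(0, 1), c(1, 1)), 0)
  # anti-collinear clips to zero by default, not with clip_negative = FALSE
  expect_equal(weighted_cosine(x, -x, rep(1, 10)), 0)
  expect_equal(weighted_cosine(x, -x, rep(1, 10), clip_negative = FALSE), -1,
    tolerance = 1e-12
  )
  s <- weighted_cosine(c(0, 0), c(1, 1), c(1, 1))
  expect_equal(as.numeric(s), 0)
  expect_true(isTRUE(attr(s, "zero_norm")))
})

test_that("raw score equals brute-force thresholded summation", {
  set.seed(4)
  for (rep in 1:100) {
    sims <- stats::runif(sample(1:30, 1))
    sc <- stats::runif(1, 0.05, 0.95)
    rs <- raw_score(sims, sc)
    expect_equal(rs$value, sum(sims[sims >= sc]))
    expect_equal(rs$n_contributing, sum(sims >= sc))
  }
  rs <- raw_score(c(0.9, 0.5, 0.3), 0.4)
  expect_equal(rs$value, 1.4)
  expect_equal(rs$n_contributing, 2L)
  expect_equal(raw_score(c(0.2, 0.3), 0.5)$value, 0)
})

test_that("raw score is monotone non-increasing in the cutoff", {
  set.seed(5)
  sims <- stats::runif(25)
  vals <- vapply(s_cut_grid(), function(sc) raw_score(sims, sc)$value,
    numeric(1)
  )
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("batch ensemble similarities agree with scalar computation", {
  b <- tiny_benchmark(seed = 21)
  cfg <- wes_config(seed = 1)
  st <- library_feature_stats(b$fp, b$desc)
  ens <- wesim:::build_ensemble(
    names(b$sets)[2], b$fp, b$desc, b$sets[[2]], cfg, st
  )
  queries <- rownames(b$fp)[c(1, 30, 55)]
  for (ch in c("binary", "continuous")) {
    feats <- if (ch == "binary") b$fp else b$desc
    batch <- wesim:::ensemble_queries_sims(
      ens, ch, feats[queries, , drop = FALSE]
    )
    chd <- ens$channels[[ch]]
    for (r in seq_along(queries)) {
      direct <- vapply(seq_len(ens$size), function(k) {
        member_id <- ens$ligand_ids[k]
        if (ch == "binary") {
          as.numeric(weighted_tanimoto(
            feats[queries[r], ], feats[member_id, ],
            chd$weights, chd$selected
          ))
        } else {
          as.numeric(weighted_cosine(
            feats[queries[r], ], feats[member_id, ],
            chd$weights, chd$selected
          ))
        }
      }, numeric(1))
      expect_equal(as.numeric(batch[r, ]), direct, tolerance = 1e-12)
    }
  }
})

test_that("the cutoff scan maximizes Z-score AUC with smallest-tie rule", {
  set.seed(6)
  # two proteins, synthetic similarity vectors with a known sweet spot
  null_sims <- list(
    list(sims = matrix(stats::runif(200, 0, 0.4), 20), size = 10),
    list(sims = matrix(stats::runif(200, 0, 0.4), 20), size = 14)
  )
  pair_sims <- c(
    lapply(1:20, function(i) stats::runif(10, 0.5, 0.9)), # positives
    lapply(1:20, function(i) stats::runif(10, 0, 0.35)) # negatives
  )
  labels <- rep(c(TRUE, FALSE), each = 20)
  res <- scan_s_cut(pair_sims, rep(c(10L, 14L), 20), labels, null_sims)
  expect_equal(res$auc, 1) # separable by construction
  # ties toward the smallest grid value: AUC is 1 on a whole range
  flat <- res$profile$s_cut[res$profile$auc == 1]
  expect_equal(res$s_cut, min(flat))
  expect_true(res$s_cut > 0 && res$s_cut < 1)
})
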