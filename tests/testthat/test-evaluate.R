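test_that("confusion metrics agree with independent arithmetic", {
  set.seed(61)
  for (rep in 1:100) {
    cnt <- sample(1:200, 4)
    ours <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    ref <- oracle_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    for (m in names(ref)) expect_identical(ours[[m]], ref[[m]])
  }
  # the headline-style table: TP=85 FN=15 TN=71 FP=29
  m <- confusion_metrics(tp = 85, tn = 71, fp = 29, fn = 15)
  expect_equal(m$SEN, 0.85)
  expect_equal(m$SPE, 0.71)
  expect_equal(m$ACC, 0.78)
  expect_equal(m$PRE, 85 / 114, tolerance = 1e-12)
  perfect <- confusion_metrics(10, 10, 0, 0)
  expect_true(all(unlist(perfect[c("ACC", "SEN", "SPE", "PRE", "F1")]) == 1))
  expect_warning(und <- confusion_metrics(0, 5, 0, 3), "PRE undefined")
  expect_true(is.na(und$PRE))
})

test_that("rank-based AUC equals the O(n^2) pair-counting oracle", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    scores <- sample(stats::rnorm(n %/% 2), n, replace = TRUE) # force ties
    labels <- stats::runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels),
      tolerance = 1e-12
    )
  }
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE)), 1)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC of label-independent scores is near one half", {
  set.seed(63)
  scores <- stats::rnorm(10000)
  labels <- stats::runif(10000) < 0.5
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.02)
})

test_that("rank AUC agrees with pROC on a shared example", {
  set.seed(64)
  scores <- stats::rnorm(300)
  labels <- stats::runif(300) < 0.5 + 0.3 * (scores > 0)
  expect_equal(
    roc_auc(scores, labels),
    as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
    tolerance = 1e-12
  )
})

test_that("LOOCV yields one held-out score per pair, order-independently", {
  b <- tiny_benchmark(seed = 14)
  cfg <- wes_config(seed = 2)
  cv <- wes_loocv(b$fp, b$desc, b$sets, b$pairs, cfg)
  expect_equal(nrow(cv$pairs), nrow(b$pairs))
  perm <- sample(nrow(b$pairs))
  cv2 <- wes_loocv(b$fp, b$desc, b$sets, b$pairs[perm, ], cfg)
  key <- function(d) paste(d$protein_id, d$ligand_id)
  reord <- match(key(cv$pairs), key(cv2$pairs))
  expect_equal(cv$pairs$z_binary, cv2$pairs$z_binary[reord],
    tolerance = 1e-12
  )
  expect_equal(cv$pairs$z_continuous, cv2$pairs$z_continuous[reord],
    tolerance = 1e-12
  )
})

test_that("held-out positives never see themselves in the fitted state", {
  # the held-out z from LOOCV must equal the z of a model fit on data with
  # the pair excluded (same frozen cutoff), i.e. no leakage via weights,
  # selections or null regressions
  b <- tiny_benchmark(seed = 15)
  cfg <- wes_config(seed = 3)
  cv <- wes_loocv(b$fp, b$desc, b$sets, b$pairs, cfg, refit = "full")
  sc <- lapply(cv$model$channels, `[[`, "s_cut")
  pos_rows <- which(b$pairs$label == 1)[c(1, 7)]
  for (i in pos_rows) {
    p <- b$pairs$protein_id[i]
    l <- b$pairs$ligand_id[i]
    sets2 <- b$sets
    sets2[[p]] <- setdiff(sets2[[p]], l)
    pairs2 <- b$pairs[-i, ]
    m2 <- wes_fit(b$fp, b$desc, sets2, pairs2, cfg, s_cut = sc)
    pred <- predict(m2,
      fp = b$fp[l, , drop = FALSE],
      desc = b$desc[l, , drop = FALSE], targets = p
    )
    expect_equal(cv$pairs$z_binary[i], pred$z_binary, tolerance = 1e-10)
    expect_equal(cv$pairs$z_continuous[i], pred$z_continuous,
      tolerance = 1e-10
    )
  }
})

test_that("duplicating an unrelated pair leaves a held-out score unchanged", {
  b <- tiny_benchmark(seed = 16)
  cfg <- wes_config(seed = 3)
  cv1 <- wes_loocv(b$fp, b$desc, b$sets, b$pairs, cfg)
  # duplicate a negative pair for a different protein: no trainable state
  # consumed by pair 1 changes (labels enter only threshold pooling)
  i <- which(b$pairs$label == 1)[1]
  other <- which(
    b$pairs$label == 0 & b$pairs$protein_id != b$pairs$protein_id[i]
  )[1]
  pairs2 <- rbind(b$pairs, b$pairs[other, ])
  cv2 <- wes_loocv(b$fp, b$desc, b$sets, pairs2, cfg)
  expect_equal(cv1$pairs$z_binary[i], cv2$pairs$z_binary[i],
    tolerance = 1e-12
  )
  expect_equal(cv1$pairs$z_continuous[i], cv2$pairs$z_continuous[i],
    tolerance = 1e-12
  )
})

test_that("1NN baseline: max-Tc statistic, calls and adjusted hit rate", {
  b <- tiny_benchmark(seed = 17)
  res <- one_nn_baseline(b$fp, b$sets, b$pairs)
  expect_length(res$tc, nrow(b$pairs))
  expect_true(all(res$tc >= 0 & res$tc <= 1))
  # a set member queried against its own set scores its nearest analog,
  # never itself; an exact duplicate elsewhere in the set gives Tc = 1
  p <- names(b$sets)[1]
  fp2 <- b$fp
  dup <- b$sets[[p]][1:2]
  fp2[dup[2], ] <- fp2[dup[1], ]
  tc <- max_tanimoto(fp2, b$sets, data.frame(
    protein_id = p, ligand_id = dup[1], stringsAsFactors = FALSE
  ))
  expect_equal(tc, 1)
  # adjusted hit rate: add-one smoothing over confirmed/predicted
  expect_equal(
    res$adjusted_hit_rate,
    (res$metrics$counts[["TP"]] + 1) / (sum(res$calls) + 1)
  )
  # degenerate no-prediction case: (0+1)/(0+1) = 1, flagged uninformative
  # (precision is undefined there, which warns by design)
  res0 <- suppressWarnings(
    one_nn_baseline(b$fp, b$sets, b$pairs, threshold = 1.5)
  )
  expect_equal(res0$adjusted_hit_rate, 1)
  expect_true(res0$uninformative)
  # bin table covers [0,1] and TP counts never exceed positives per bin
  expect_equal(sum(res$bins$n_pos) + sum(res$bins$n_neg), nrow(b$pairs))
  expect_true(all(res$bins$tp <= res$bins$n_pos))
})

test_that("warned single-ligand sets are scored, not dropped", {
  b <- tiny_benchmark(seed = 18)
  sets <- b$sets
  p <- names(sets)[1]
  keep1 <- sets[[p]][1]
  sets[[p]] <- keep1
  pairs <- b$pairs[
    b$pairs$protein_id != p | b$pairs$ligand_id == keep1,
  ]
  cv <- wes_loocv(b$fp, b$desc, sets, pairs, wes_config(seed = 2))
  i <- which(pairs$protein_id == p & pairs$ligand_id == keep1)
  expect_true(cv$pairs$flagged[i])
  expect_true(is.finite(cv$pairs$z_binary[i]))
})
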