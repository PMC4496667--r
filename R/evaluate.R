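#' Leave-one-out cross-validation of the weighted ensemble model
#'
#' Scores every labeled pair with that pair excluded from the trainable
#' state. For a held-out positive pair the ligand is removed from its
#' protein's ensemble: the protein's feature weights and selections are
#' refit with the ligand counted in the background remainder, the ligand is
#' rescored against the reduced set, and (with `refit = "full"`, the
#' default) the protein's null moments and the global null regressions are
#' refit at the reduced set size. Held-out negative pairs do not contribute
#' to any trainable component, so their scores equal the base-model scores.
#' The similarity cutoff is a hyperparameter fixed once by the global scan
#' before cross-validation (pass `s_cut` to freeze it externally).
#'
#' Decision thresholds and the hybrid class densities are then derived from
#' the pooled held-out scores: the KDE pair is fit per class on the held-out
#' (z1, z2) points and evaluated leave-self-out, and the Z and likelihood
#' thresholds are the F1 maximizers over the pooled scores.
#'
#' @param fp,desc,sets,pairs,config As in [wes_fit()].
#' @param refit `"full"` (exact per-pair refit of ensemble weights and null
#'   regressions) or `"ensemble"` (weights only; null regressions frozen at
#'   the base fit — cheaper, near-identical at realistic sizes).
#' @param s_cut Optional fixed per-channel cutoff forwarded to [wes_fit()].
#' @param progress Print a dot every 100 pairs.
#' @return A list: `pairs` (data frame with per-pair held-out `z_*`,
#'   `likelihood`, `label`, `flagged`), `thresholds`, `metrics` (per channel
#'   and hybrid), `auc` (per channel and hybrid), `model` (the base fit).
#' @export
wes_loocv <- function(fp, desc, sets, pairs, config = wes_config(),
                      refit = c("full", "ensemble"), s_cut = NULL,
                      progress = FALSE) {
  refit <- match.arg(refit)
  base <- wes_fit(fp, desc, sets, pairs, config, s_cut = s_cut)
  stats <- library_feature_stats(fp, desc)
  labels <- as.logical(pairs$label)
  n <- nrow(pairs)
  z_mat <- base$training$z # held-out z starts as training z (negatives keep it)
  flagged <- logical(n)
  pair_prot <- match(pairs$protein_id, names(base$ensembles))
  # per-pair, per-channel abstention flags (featureless target ensemble)
  abst <- vapply(config$channels, function(ch) {
    no_feat <- vapply(
      base$ensembles, function(e) length(e$channels[[ch]]$selected) == 0L,
      logical(1)
    )
    no_feat[pair_prot]
  }, logical(n))
  if (is.null(dim(abst))) abst <- matrix(abst, nrow = n)

  member_of <- paste(pairs$protein_id, pairs$ligand_id, sep = "\r") %in%
    unlist(lapply(names(sets), function(p) paste(p, sets[[p]], sep = "\r")))

  for (i in seq_len(n)) {
    if (progress && i %% 100L == 0L) cat(".")
    if (!member_of[i]) next # pair absent from ensembles: nothing to refit
    p <- pairs$protein_id[i]
    l <- pairs$ligand_id[i]
    reduced <- setdiff(sets[[p]], l)
    if (length(reduced) < 2L) {
      flagged[i] <- TRUE
      next # scored with the full ensemble; too small to refit
    }
    ens <- build_ensemble(p, fp, desc, reduced, config, stats = stats)
    for (ch in config$channels) {
      if (length(ens$channels[[ch]]$selected) == 0L) {
        z_mat[i, ch] <- 0 # featureless refit ensemble: abstain
        abst[i, match(ch, config$channels)] <- TRUE
        next
      }
      abst[i, match(ch, config$channels)] <- FALSE
      chf <- base$channels[[ch]]
      feats <- channel_matrix(fp, desc, ch)
      sims <- ensemble_query_sims(ens, ch, feats[l, ])
      raw <- sum(sims[sims >= chf$s_cut])
      null <- chf$null
      if (refit == "full") {
        ns <- null_sims_for(ens, ch, fp, desc, config)
        mom_raw <- apply(ns$sims, 1L, function(s) sum(s[s >= chf$s_cut]))
        tab <- null$table
        row <- match(p, names(base$ensembles))
        tab$size[row] <- ens$size
        tab$mu[row] <- mean(mom_raw)
        tab$sigma[row] <- stats::sd(mom_raw)
        null <- fit_null(tab$size, tab$mu, tab$sigma,
          channel = ch,
          sigma_floor = config$sigma_floor
        )
      }
      z_mat[i, ch] <- z_score(raw, null, ens$size)
    }
  }
  if (progress) cat("\n")

  thresholds <- list()
  metrics <- list()
  auc <- list()
  out <- data.frame(
    pairs, z_binary = NA_real_, z_continuous = NA_real_,
    likelihood = NA_real_, flagged = flagged, stringsAsFactors = FALSE
  )
  for (ch in config$channels) {
    z <- z_mat[, ch]
    out[[paste0("z_", ch)]] <- z
    thr <- choose_z_threshold(z, labels)
    thresholds[[ch]] <- thr$threshold
    metrics[[ch]] <- confusion_metrics(
      tp = sum(z > thr$threshold & labels),
      tn = sum(z <= thr$threshold & !labels),
      fp = sum(z > thr$threshold & !labels),
      fn = sum(z <= thr$threshold & labels)
    )
    auc[[ch]] <- roc_auc(z, labels)
  }

  if (length(config$channels) == 2L) {
    pts <- z_mat[, c("binary", "continuous"), drop = FALSE]
    priors <- if (config$priors == "empirical") {
      c(mean(labels), mean(!labels))
    } else {
      c(0.5, 0.5)
    }
    # full-abstention pairs carry no evidence: likelihood = prior, and
    # they are excluded from the class-conditional densities
    use <- rowSums(!abst) > 0
    L <- rep(priors[1L], n)
    if (sum(labels & use) >= 2L && sum(!labels & use) >= 2L) {
      pos_rows <- which(labels & use)
      neg_rows <- which(!labels & use)
      kde_pos <- fit_kde(pts[pos_rows, , drop = FALSE],
        config$bandwidth_rule)
      kde_neg <- fit_kde(pts[neg_rows, , drop = FALSE],
        config$bandwidth_rule)
      # leave-self-out: a point never contributes its own kernel
      urows <- which(use)
      ex_pos <- match(urows, pos_rows)
      ex_neg <- match(urows, neg_rows)
      L[urows] <- likelihood(
        pts[urows, 1L], pts[urows, 2L], kde_pos, kde_neg, priors,
        exclude_pos = ex_pos, exclude_neg = ex_neg
      )
    }
    out$likelihood <- L
    th <- choose_theta(L, labels)
    thresholds$theta <- th$threshold
    metrics$hybrid <- confusion_metrics(
      tp = sum(L > th$threshold & labels),
      tn = sum(L <= th$threshold & !labels),
      fp = sum(L > th$threshold & !labels),
      fn = sum(L <= th$threshold & labels)
    )
    auc$hybrid <- roc_auc(L, labels)
  }
  list(
    pairs = out, thresholds = thresholds, metrics = metrics, auc = auc,
    model = base
  )
}

#' Maximum plain Tanimoto of each pair's query to its target set
#'
#' The nearest-neighbour statistic: unweighted Tanimoto over the full
#' fingerprint, maximized over the target's set members.
#'
#' @param fp Fingerprint matrix (library + queries; row names = ids).
#' @param sets Named list of target member ids.
#' @param pairs Data frame `protein_id, ligand_id`.
#' @return Numeric vector of max-Tc values (NA, with a warning, for pairs
#'   whose target set is empty).
#' @export
max_tanimoto <- function(fp, sets, pairs) {
  eq_w <- rep(1, ncol(fp))
  vapply(seq_len(nrow(pairs)), function(i) {
    members <- setdiff(sets[[pairs$protein_id[i]]], pairs$ligand_id[i])
    if (length(members) == 0L) {
      warning("empty target set; pair skipped", call. = FALSE)
      return(NA_real_)
    }
    s <- ensemble_similarities(
      fp[pairs$ligand_id[i], ], fp[members, , drop = FALSE],
      eq_w, seq_along(eq_w), "binary"
    )
    max(s)
  }, numeric(1))
}

#' One-nearest-neighbour baseline
#'
#' Calls a pair positive when the query's maximum plain Tanimoto to the
#' target's ligand set exceeds a threshold (chosen at the baseline's own F1
#' optimum unless supplied), and tabulates true-positive rates in Tc bins
#' alongside the add-one-smoothed adjusted hit rate
#' `(confirmed + 1) / (predicted + 1)`, which stays defined (and equal to
#' 1, flagged as uninformative) when nothing is predicted.
#'
#' @param fp,sets,pairs As in [max_tanimoto()]; `pairs` needs a `label`
#'   column.
#' @param threshold Optional fixed decision threshold.
#' @param bin_width Tc bin width (default 0.05).
#' @return A list: `tc` (per-pair max Tc), `threshold`, `metrics`,
#'   `adjusted_hit_rate`, `bins` (data frame with per-bin positive counts
#'   and TP rates), `calls`.
#' @export
one_nn_baseline <- function(fp, sets, pairs, threshold = NULL,
                            bin_width = 0.05) {
  labels <- as.logical(pairs$label)
  tc <- max_tanimoto(fp, sets, pairs)
  keep <- !is.na(tc)
  if (is.null(threshold)) {
    threshold <- f1_threshold_scan(tc[keep], labels[keep])$threshold
  }
  calls <- !is.na(tc) & tc > threshold
  mt <- confusion_metrics(
    tp = sum(calls & labels), tn = sum(!calls & !labels),
    fp = sum(calls & !labels), fn = sum(!calls & labels)
  )
  n_pred <- sum(calls)
  ahr <- (sum(calls & labels) + 1) / (n_pred + 1)
  edges <- seq(0, 1, by = bin_width)
  bin <- cut(pmin(tc, 1 - 1e-12), edges, right = FALSE, include.lowest = TRUE)
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    in_b <- !is.na(bin) & bin == b
    data.frame(
      bin = b,
      lower = edges[match(b, levels(bin))],
      n_pos = sum(in_b & labels),
      n_neg = sum(in_b & !labels),
      tp = sum(in_b & labels & calls),
      tp_rate = if (sum(in_b & labels)) {
        sum(in_b & labels & calls) / sum(in_b & labels)
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }))
  list(
    tc = tc, threshold = threshold, metrics = mt,
    adjusted_hit_rate = ahr, uninformative = n_pred == 0L,
    bins = bins, calls = calls
  )
}

#' Scaffold-hopping contrast: weighted ensemble model versus 1NN
#'
#' Trains the model on a multi-cluster benchmark, scores a probe set
#' containing close analogs, cluster hoppers and decoys (see
#' [generate_scaffold_probes()]), and compares per-Tc-bin true-positive
#' rates of the model's calls against the 1NN baseline thresholded at its
#' own F1 optimum on the same probes.
#'
#' @param benchmark A `wes_benchmark` (multi-cluster).
#' @param probes Probe set from [generate_scaffold_probes()].
#' @param config Model configuration.
#' @param model Optional pre-trained `wes_model` (skips fitting).
#' @param bin_width Tc bin width.
#' @return A list: `bins` (per-bin WES and 1NN TP rates), `onenn`
#'   (baseline object), `predictions`, `model`, `tc`.
#' @export
scaffold_contrast <- function(benchmark, probes, config = wes_config(),
                              model = NULL, bin_width = 0.05) {
  if (is.null(model)) {
    model <- wes_fit(
      benchmark$fp, benchmark$desc, benchmark$sets,
      benchmark$pairs, config
    )
  }
  pred <- do.call(rbind, lapply(seq_len(nrow(probes$pairs)), function(i) {
    predict(model,
      fp = probes$fp[i, , drop = FALSE],
      desc = probes$desc[i, , drop = FALSE],
      targets = probes$pairs$protein_id[i]
    )
  }))
  labels <- as.logical(probes$pairs$label)

  # 1NN on the probe pairs: library fingerprints for the sets, probe rows
  all_fp <- rbind(benchmark$fp, probes$fp)
  tc <- max_tanimoto(all_fp, benchmark$sets, probes$pairs)
  onenn <- one_nn_baseline(all_fp, benchmark$sets, probes$pairs,
    bin_width = bin_width
  )
  edges <- seq(0, 1, by = bin_width)
  bin <- cut(pmin(tc, 1 - 1e-12), edges, right = FALSE, include.lowest = TRUE)
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    in_b <- !is.na(bin) & bin == b
    np <- sum(in_b & labels)
    data.frame(
      bin = b, lower = edges[match(b, levels(bin))], n_pos = np,
      wes_tp = sum(in_b & labels & pred$call),
      wes_tp_rate = if (np) sum(in_b & labels & pred$call) / np else NA_real_,
      onenn_tp = sum(in_b & labels & onenn$calls),
      onenn_tp_rate = if (np) {
        sum(in_b & labels & onenn$calls) / np
      } else {
        NA_real_
      },
      stringsAsFactors = FALSE
    )
  }))
  list(bins = bins, onenn = onenn, predictions = pred, model = model, tc = tc)
}
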