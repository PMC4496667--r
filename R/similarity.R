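#' Weighted Tanimoto similarity between two binary feature vectors
#'
#' \deqn{S(a, b) = \frac{\sum_{i \in idx} w_i (a_i \wedge b_i)}
#'                      {\sum_{i \in idx} w_i (a_i \vee b_i)}}
#' restricted to the selected feature indices. Equal weights recover the
#' classic Tanimoto coefficient. An empty OR-support (no selected bit set in
#' either molecule) returns 0 by convention, flagged via attribute.
#'
#' @param a,b Binary vectors of equal length.
#' @param w Non-negative weight vector of the same length.
#' @param idx Selected feature indices (default: all).
#' @return Similarity in `[0, 1]`.
#' @export
weighted_tanimoto <- function(a, b, w, idx = seq_along(a)) {
  stopifnot(length(a) == length(b), length(w) == length(a), all(w >= 0))
  a <- a[idx]
  b <- b[idx]
  w <- w[idx]
  num <- sum(w * (a & b))
  den <- sum(w * (a | b))
  if (den == 0) {
    s <- 0
    attr(s, "empty_support") <- TRUE
    return(s)
  }
  num / den
}

#' Weighted cosine similarity between two continuous feature vectors
#'
#' Cosine of the elementwise weighted sub-vectors
#' \eqn{\langle w \circ x, w \circ y\rangle / (|w \circ x| |w \circ y|)}
#' on the selected indices, with negative values clipped to 0 so both
#' feature channels share the `(0, 1)` similarity-cutoff domain. A zero-norm
#' weighted vector yields 0, flagged via attribute.
#'
#' @param x,y Numeric vectors of equal length.
#' @param w Non-negative weight vector.
#' @param idx Selected feature indices (default: all).
#' @param clip_negative Clip negative cosines to 0 (default `TRUE`).
#' @return Similarity in `[0, 1]` (in `[-1, 1]` if `clip_negative = FALSE`).
#' @export
weighted_cosine <- function(x, y, w, idx = seq_along(x), clip_negative = TRUE) {
  stopifnot(length(x) == length(y), length(w) == length(x), all(w >= 0))
  wx <- (w * x)[idx]
  wy <- (w * y)[idx]
  nx <- sqrt(sum(wx^2))
  ny <- sqrt(sum(wy^2))
  if (nx == 0 || ny == 0) {
    s <- 0
    attr(s, "zero_norm") <- TRUE
    return(s)
  }
  s <- sum(wx * wy) / (nx * ny)
  if (clip_negative) s <- max(s, 0)
  min(s, 1)
}

#' Pairwise similarities of one query against an ensemble (vectorized)
#'
#' Internal workhorse: similarity of a single query feature vector to every
#' member of a target's ligand set, on the selected features with the
#' ensemble's weights. Binary channel = weighted Tanimoto, continuous
#' channel = clipped weighted cosine.
#'
#' @param query Feature vector (full-length; subsetting is internal).
#' @param members Matrix of member feature vectors (rows, full-length).
#' @param w Full-length weight vector.
#' @param idx Selected feature indices.
#' @param channel `"binary"` or `"continuous"`.
#' @return Numeric vector of similarities, one per member.
#' @export
ensemble_similarities <- function(query, members, w, idx,
                                  channel = c("binary", "continuous")) {
  channel <- match.arg(channel)
  k <- nrow(members)
  if (length(idx) == 0L) {
    return(rep(0, k))
  }
  ws <- w[idx]
  q <- query[idx]
  m <- members[, idx, drop = FALSE]
  if (channel == "binary") {
    num <- as.numeric(m %*% (ws * q))
    den <- as.numeric(m %*% ws) + sum(ws * q) - num
    s <- ifelse(den == 0, 0, num / den)
  } else {
    wq <- ws * q
    mw <- sweep(m, 2L, ws, `*`)
    num <- as.numeric(mw %*% wq)
    nq <- sqrt(sum(wq^2))
    nm <- sqrt(rowSums(mw^2))
    den <- nm * nq
    s <- ifelse(den == 0, 0, pmin(pmax(num / den, 0), 1))
  }
  s
}

#' Ensemble raw score of a query molecule
#'
#' Sum of the query's weighted similarities to the target's ligand-set
#' members, keeping only pairwise similarities at or above the cutoff
#' `s_cut`; similarities below the cutoff are discarded and do not
#' contribute to the overall ensemble similarity.
#'
#' @param sims Numeric vector of pairwise similarities to the set members
#'   (from [ensemble_similarities()]).
#' @param s_cut Similarity cutoff in `(0, 1)`.
#' @return List with `value` (the raw score) and `n_contributing`.
#' @export
raw_score <- function(sims, s_cut) {
  stopifnot(s_cut > 0, s_cut < 1)
  keep <- sims >= s_cut
  list(value = sum(sims[keep]), n_contributing = sum(keep))
}

#' The similarity-cutoff grid
#'
#' `{0.01, 0.02, ..., 0.99}` — the scanned domain of the global cutoff.
#' @return Numeric vector of 99 grid values.
#' @export
s_cut_grid <- function() seq(0.01, 0.99, by = 0.01)

#' Choose the global similarity cutoff by ROC-AUC scan
#'
#' For each grid value the labeled pairs' raw scores are thresholded at that
#' cutoff, converted to Z-scores with a null model calibrated at the same
#' cutoff, and scored by ROC AUC; the cutoff with the highest AUC wins, ties
#' toward the smallest cutoff. Pairwise similarities do not depend on the
#' cutoff, so the scan reuses precomputed similarity vectors.
#'
#' @param pair_sims List over labeled pairs; element i holds the similarity
#'   vector of pair i's query against its target's set members.
#' @param pair_sizes Integer vector: target ligand-set size per pair.
#' @param labels Logical vector of pair labels.
#' @param null_sims List over proteins: each element a list with `sims`
#'   (matrix: random ligands x set members similarity) and `size` (the
#'   protein's set size), used to refit the null at every cutoff.
#' @param grid Cutoff grid (default [s_cut_grid()]).
#' @param sigma_floor Lower bound on the null standard deviation.
#' @return List with `s_cut`, `auc`, and the scan `profile` data frame
#'   (`valid` marks cutoffs with a non-degenerate null).
#' @details Cutoffs where the null model degenerates — the sigma regression
#'   predicts no random-score variance at the median training set size,
#'   because (almost) no random ligand reaches the cutoff — are excluded
#'   from the selection: a null with zero variance cannot calibrate a
#'   Z-score. If every cutoff is degenerate the full grid is used as a
#'   fallback.
#' @export
scan_s_cut <- function(pair_sims, pair_sizes, labels, null_sims,
                       grid = s_cut_grid(), sigma_floor = 1e-6) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both label classes required")
  med_size <- stats::median(
    vapply(null_sims, function(x) as.numeric(x$size), numeric(1))
  )
  aucs <- numeric(length(grid))
  valid <- logical(length(grid))
  for (g in seq_along(grid)) {
    sc <- grid[g]
    nm <- fit_null_from_sims(null_sims, sc, sigma_floor = sigma_floor)
    raw <- vapply(pair_sims, function(s) sum(s[s >= sc]), numeric(1))
    z <- z_score(raw, nm, pair_sizes)
    aucs[g] <- roc_auc(z, labels)
    valid[g] <- (nm$alpha2 * med_size + nm$beta2) > sigma_floor
  }
  pool <- if (any(valid)) which(valid) else seq_along(grid)
  best <- pool[which(aucs[pool] == max(aucs[pool]))[1L]]
  list(
    s_cut = grid[best], auc = aucs[best],
    profile = data.frame(s_cut = grid, auc = aucs, valid = valid)
  )
}
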