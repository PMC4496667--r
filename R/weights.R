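#' Per-bit one-sided Fisher exact p-values for a ligand ensemble
#'
#' For every fingerprint bit, tests over-representation of the bit in a
#' target's ligand set against the remaining training ligands (one-sided
#' Fisher exact test on the 2x2 table bit-on/off x in-set/rest). The
#' background is the full training ligand library; the set's own rows are
#' removed from it before the table is formed so the margins are disjoint.
#'
#' The p-value for bit i with k_set of n_set set ligands and k_rest of
#' n_rest remaining ligands carrying the bit is the hypergeometric upper
#' tail P(X >= k_set) with X ~ Hypergeom(n_set + n_rest, k_set + k_rest,
#' n_set), computed vectorized via [stats::phyper()].
#'
#' @param ensemble_fp Binary matrix (set ligands x bits).
#' @param background_fp Binary matrix (library ligands x bits), same bit
#'   columns. May or may not contain the set rows.
#' @param set_rows Optional integer or logical index of the ensemble's rows
#'   within `background_fp`; when supplied those rows are subtracted so the
#'   background becomes "library minus set". When `NULL` the background is
#'   assumed disjoint from the set already.
#' @return Numeric vector of p-values, one per bit; bits absent from both
#'   groups get p = 1 and are reported in the `"flat_bits"` attribute.
#' @export
binary_feature_pvalues <- function(ensemble_fp, background_fp, set_rows = NULL) {
  ensemble_fp <- as.matrix(ensemble_fp)
  background_fp <- as.matrix(background_fp)
  if (nrow(ensemble_fp) == 0L) stop("empty ligand set")
  if (ncol(ensemble_fp) != ncol(background_fp)) {
    stop("ensemble and background must share the same bit columns")
  }
  n_set <- nrow(ensemble_fp)
  k_set <- colSums(ensemble_fp)
  k_bg <- colSums(background_fp)
  n_bg <- nrow(background_fp)
  if (!is.null(set_rows)) {
    if (is.logical(set_rows)) set_rows <- which(set_rows)
    k_bg <- k_bg - k_set
    n_bg <- n_bg - length(set_rows)
    if (n_bg < 0 || any(k_bg < -1e-9)) {
      stop("set_rows inconsistent with background matrix")
    }
  }
  n_rest <- n_bg
  k_rest <- pmax(k_bg, 0)
  # upper tail: P(X >= k_set)
  p <- stats::phyper(k_set - 1, k_set + k_rest, n_set + n_rest - k_set - k_rest,
    n_set,
    lower.tail = FALSE
  )
  p <- pmin(pmax(p, 0), 1)
  flat <- which(k_set + k_rest == 0)
  p[flat] <- 1
  attr(p, "flat_bits") <- flat
  p
}

#' Per-descriptor Wilcoxon rank-sum p-values for a ligand ensemble
#'
#' Two-sample two-sided rank-sum test of each continuous descriptor, set
#' versus background-minus-set. Small groups (both sizes <= `exact_max`, no
#' ties) use the exact null distribution via [stats::wilcox.test()]; larger
#' problems use a vectorized normal approximation with tie correction and
#' continuity correction (the same approximation `wilcox.test` applies).
#'
#' @param ensemble_desc Numeric matrix (set ligands x descriptors).
#' @param background_desc Numeric matrix (library ligands x descriptors).
#' @param set_rows Optional index of set rows within `background_desc` to be
#'   excluded from the comparison group (see [binary_feature_pvalues()]).
#' @param exact_max Largest group size for which the exact test is used.
#' @return Numeric vector of p-values per descriptor. Zero-variance
#'   descriptors (identical pooled values) get p = 1 and are listed in the
#'   `"flat_features"` attribute.
#' @export
continuous_feature_pvalues <- function(ensemble_desc, background_desc,
                                       set_rows = NULL, exact_max = 25L) {
  ensemble_desc <- as.matrix(ensemble_desc)
  background_desc <- as.matrix(background_desc)
  if (nrow(ensemble_desc) == 0L) stop("empty ligand set")
  if (ncol(ensemble_desc) != ncol(background_desc)) {
    stop("ensemble and background must share descriptor columns")
  }
  if (!is.null(set_rows)) {
    if (is.logical(set_rows)) set_rows <- which(set_rows)
    background_desc <- background_desc[-set_rows, , drop = FALSE]
  }
  m <- nrow(ensemble_desc)
  n <- nrow(background_desc)
  if (n == 0L) stop("background empty after removing the set")
  if (m == 1L) {
    warning("single-ligand set: rank-sum test has very low power",
      call. = FALSE
    )
  }
  d <- ncol(ensemble_desc)
  p <- numeric(d)
  flat <- integer(0)
  use_exact <- m <= exact_max && n <= exact_max
  for (j in seq_len(d)) {
    x <- ensemble_desc[, j]
    y <- background_desc[, j]
    pooled <- c(x, y)
    if (max(pooled) == min(pooled)) {
      p[j] <- 1
      flat <- c(flat, j)
      next
    }
    has_ties <- anyDuplicated(pooled) > 0L
    if (use_exact && !has_ties) {
      p[j] <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    } else {
      r <- rank(pooled)
      w <- sum(r[seq_len(m)]) - m * (m + 1) / 2 # Mann-Whitney U of the set
      mu <- m * n / 2
      tie_tab <- table(pooled)
      sig2 <- m * n / 12 *
        ((m + n + 1) - sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
      if (sig2 <= 0) {
        p[j] <- 1
        flat <- c(flat, j)
        next
      }
      z <- w - mu
      z <- (z - sign(z) * 0.5) / sqrt(sig2) # continuity correction
      p[j] <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  attr(p, "flat_features") <- flat
  p
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Thin, contract-checked wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values in `[0, 1]`, order-preserving in p.
#' @export
adjust_pvalues <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Feature weights from q-values
#'
#' Significant features (q below the threshold, default 0.05) receive weight
#' `-log10(q)`; everything at or above the threshold receives weight zero.
#' Weights are therefore non-negative and strictly decreasing in q within
#' the significant range, so more strongly enriched features dominate both
#' sums of the weighted Tanimoto coefficient.
#'
#' @param q_values Adjusted p-values in `[0, 1]`.
#' @param q_threshold Significance cutoff (default 0.05).
#' @param q_floor Lower clamp on q before taking logs, guarding against
#'   infinite weights at q = 0.
#' @return Non-negative weight vector, zero where `q >= q_threshold`.
#' @export
compute_weights <- function(q_values, q_threshold = 0.05, q_floor = 1e-300) {
  stopifnot(all(q_values >= 0 & q_values <= 1), q_threshold > 0)
  w <- numeric(length(q_values))
  sig <- q_values < q_threshold
  w[sig] <- -log10(pmax(q_values[sig], q_floor))
  if (!any(sig)) {
    warning("no feature is significant at the q threshold; all weights zero",
      call. = FALSE
    )
  }
  w
}

#' Select the top-m weighted features
#'
#' Indices of the `m` largest weights among features with positive weight,
#' ties broken toward the smaller feature index. If fewer than `m` features
#' have positive weight, all of them are returned with a warning.
#'
#' @param weights Non-negative weight vector.
#' @param m Number of features to retain.
#' @return Integer vector of selected feature indices (possibly empty).
#' @export
select_features <- function(weights, m) {
  stopifnot(m >= 1, m == round(m))
  nz <- which(weights > 0)
  if (length(nz) == 0L) {
    warning("all weights are zero; empty feature selection", call. = FALSE)
    return(integer(0))
  }
  if (length(nz) < m) {
    warning(sprintf(
      "only %d features have positive weight (requested %d)",
      length(nz), m
    ), call. = FALSE)
    m <- length(nz)
  }
  ord <- nz[order(-weights[nz], nz)]
  sort(ord[seq_len(m)])
}

#' Optimize the retained feature count over a candidate grid
#'
#' Evaluates an objective callback at every candidate feature count and
#' returns the maximizer; ties are broken toward the smallest count. The
#' default objective used by the model driver is retrieval AUC of the
#' protein's own ligands against background under leave-one-out raw scoring,
#' but any `function(m) -> numeric(1)` can be supplied.
#'
#' @param candidate_ms Vector of candidate feature counts.
#' @param objective Function mapping a feature count to a scalar objective
#'   value (larger is better). Evaluation errors propagate unless every
#'   candidate fails, which is fatal with a summary.
#' @return A list with `m` (the selected count), `objective` (its value) and
#'   the full `profile` data frame.
#' @export
optimize_feature_count <- function(candidate_ms, objective) {
  stopifnot(length(candidate_ms) >= 1, is.function(objective))
  candidate_ms <- sort(unique(as.integer(candidate_ms)))
  vals <- vapply(candidate_ms, function(m) {
    v <- tryCatch(objective(m), error = function(e) NA_real_)
    if (length(v) != 1L) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (all(is.na(vals))) stop("objective failed on every candidate m")
  best <- which(vals == max(vals, na.rm = TRUE))[1L] # ascending: smallest m wins
  list(
    m = candidate_ms[best],
    objective = vals[best],
    profile = data.frame(m = candidate_ms, objective = vals)
  )
}

#' Precompute library-level feature statistics
#'
#' For ensemble weighting the comparison group is always "the library minus
#' the set", so the pooled sample is the full library: per-bit totals, per
#' descriptor pooled column ranks and tie terms can be computed once and
#' reused for every protein and every leave-one-out refit. The fast
#' p-value paths below are algebraically identical to
#' [binary_feature_pvalues()] / [continuous_feature_pvalues()] (normal
#' approximation path) called with `set_rows` against the full library.
#'
#' @param fp Binary matrix for the full ligand library.
#' @param desc Continuous matrix for the full library (or `NULL`).
#' @return An opaque list consumed by [weight_ensemble()].
#' @export
library_feature_stats <- function(fp, desc = NULL) {
  out <- list(n = nrow(fp), fp_colsums = colSums(fp))
  if (!is.null(desc)) {
    out$desc_ranks <- apply(desc, 2L, rank)
    out$tie_term <- vapply(seq_len(ncol(desc)), function(j) {
      tt <- tabulate(match(desc[, j], unique(desc[, j])))
      sum(tt^3 - tt)
    }, numeric(1))
    out$desc_flat <- vapply(
      seq_len(ncol(desc)),
      function(j) max(desc[, j]) == min(desc[, j]), logical(1)
    )
  }
  out
}

# fast Fisher path against the precomputed library stats (internal)
fast_binary_pvalues <- function(stats, fp, set_rows) {
  m <- length(set_rows)
  k_set <- colSums(fp[set_rows, , drop = FALSE])
  k_rest <- stats$fp_colsums - k_set
  n_rest <- stats$n - m
  p <- stats::phyper(k_set - 1, k_set + k_rest,
    m + n_rest - k_set - k_rest, m,
    lower.tail = FALSE
  )
  p[k_set + k_rest == 0] <- 1
  pmin(pmax(p, 0), 1)
}

# fast rank-sum path (normal approximation, tie + continuity corrected)
fast_continuous_pvalues <- function(stats, set_rows) {
  m <- length(set_rows)
  n <- stats$n - m
  w <- colSums(stats$desc_ranks[set_rows, , drop = FALSE]) - m * (m + 1) / 2
  nn <- stats$n
  sig2 <- m * n / 12 * ((nn + 1) - stats$tie_term / (nn * (nn - 1)))
  z <- w - m * n / 2
  z <- (z - sign(z) * 0.5) / sqrt(pmax(sig2, .Machine$double.eps))
  p <- pmin(1, 2 * stats::pnorm(-abs(z)))
  p[sig2 <= 0 | stats$desc_flat] <- 1
  p
}

#' Weight one protein ensemble on both feature channels
#'
#' Convenience driver running the per-channel enrichment test, BH
#' adjustment, weighting and top-m selection for one target.
#'
#' @param fp,desc Binary / continuous matrices for the full ligand library.
#' @param set_rows Index of the target's ligand rows within the library.
#' @param q_threshold Significance cutoff for both channels.
#' @param m_binary,m_continuous Feature-count caps per channel; the retained
#'   count is `min(cap, number of significant features)`.
#' @param stats Optional precomputed [library_feature_stats()]; built on the
#'   fly when absent.
#' @return List with per-channel `p`, `q`, `weights`, `selected`.
#' @export
weight_ensemble <- function(fp, desc, set_rows, q_threshold = 0.05,
                            m_binary = 256L, m_continuous = 64L,
                            stats = NULL) {
  if (is.null(stats)) stats <- library_feature_stats(fp, desc)
  one_channel <- function(p, m_cap) {
    q <- adjust_pvalues(as.numeric(p))
    w <- suppressWarnings(compute_weights(q, q_threshold))
    sel <- if (any(w > 0)) {
      suppressWarnings(select_features(w, min(m_cap, sum(w > 0))))
    } else {
      integer(0)
    }
    list(p = as.numeric(p), q = q, weights = w, selected = sel)
  }
  out <- list(
    binary = one_channel(fast_binary_pvalues(stats, fp, set_rows), m_binary)
  )
  if (!is.null(desc)) {
    out$continuous <- one_channel(
      fast_continuous_pvalues(stats, set_rows), m_continuous
    )
  }
  out
}
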