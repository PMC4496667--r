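#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All randomness in the package flows from one master seed. Independent
#' random streams (background ligands, per-protein signatures, negative
#' sampling, null draws, ...) are derived deterministically from the master
#' seed and a string label, so adding a stream never perturbs the others.
#'
#' @param seed Master seed (single integer).
#' @param key Stream label (character scalar).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' split_seed(7, "background") != split_seed(7, "signatures")
split_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(key))
  # 32-bit FNV-1a over the label bytes, folded with the seed; kept < 2^31 - 1
  h <- 2166136261
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 48271) %% 2147483646)
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney rank
#' statistic; ties receive average ranks, so constant scores give 0.5.
#'
#' @param scores Numeric vector of scores (higher = more positive-like).
#' @param labels Logical or 0/1 vector of true classes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_auc requires both classes to be present")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion-matrix metric suite
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1 from raw
#' confusion counts. Ratios with zero denominators are returned as `NA` with
#' a warning rather than silently coerced.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A list with elements `ACC`, `SEN`, `SPE`, `PRE`, `F1` and the
#'   echoed `counts`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated pairs")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  acc <- (tp + tn) / total
  sen <- safe_div(tp, tp + fn, "SEN")
  spe <- safe_div(tn, tn + fp, "SPE")
  pre <- safe_div(tp, tp + fp, "PRE")
  f1 <- if (is.na(sen) || is.na(pre) || (sen + pre) == 0) {
    NA_real_
  } else {
    2 * pre * sen / (pre + sen)
  }
  list(ACC = acc, SEN = sen, SPE = spe, PRE = pre, F1 = f1, counts = counts)
}

#' Choose a decision threshold by maximizing F1
#'
#' Scans every observed score as a candidate threshold, with calls made by
#' `score > threshold`, and returns the threshold with the highest F1; ties
#' are broken toward the smallest threshold. One extra candidate below the
#' minimum score is included so that "call everything positive" is in the
#' scanned family.
#'
#' @param scores Numeric scores.
#' @param labels True classes (logical or 0/1).
#' @return A list with `threshold`, `f1`, and the full `scan` data frame.
#' @export
f1_threshold_scan <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  if (!any(labels) || all(labels)) stop("both classes required for F1 scan")
  cand <- sort(unique(c(min(scores) - 1, scores)))
  n_pos <- sum(labels)
  # tp(t) = positives with score > t: use cumulative counts over sorted scores
  f1s <- vapply(cand, function(t) {
    call <- scores > t
    tp <- sum(call & labels)
    fp <- sum(call & !labels)
    if (tp == 0) return(0)
    pre <- tp / (tp + fp)
    sen <- tp / n_pos
    2 * pre * sen / (pre + sen)
  }, numeric(1))
  best <- which(f1s == max(f1s))[1L] # cand sorted ascending: smallest wins ties
  list(
    threshold = cand[best],
    f1 = f1s[best],
    scan = data.frame(threshold = cand, f1 = f1s)
  )
}
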