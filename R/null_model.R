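#' Sample random-ligand raw scores against one ensemble
#'
#' Draws `n_random` ligands (without replacement) from the full training
#' ligand pool, computes each one's similarity vector against the target's
#' set members and returns the raw scores at the given cutoff. The sampled
#' similarity matrix is returned too so null moments can be re-thresholded
#' at other cutoffs without resampling.
#'
#' @param features Full-library feature matrix (ligands x features).
#' @param members Member feature matrix of the target's ligand set.
#' @param w,idx,channel Ensemble weighting as in [ensemble_similarities()].
#' @param s_cut Similarity cutoff.
#' @param n_random Number of random ligands (default 50).
#' @param seed Integer seed; the draw is reproducible.
#' @return List with `raw` (numeric `n_random` raw scores), `sims` (matrix
#'   `n_random` x set size), `sampled` (row indices drawn).
#' @export
sample_random_raw_scores <- function(features, members, w, idx, channel,
                                     s_cut, n_random = 50L, seed = 1L) {
  n_pool <- nrow(features)
  if (n_pool < n_random) {
    stop(sprintf(
      "ligand pool (%d) smaller than requested random set (%d)",
      n_pool, n_random
    ))
  }
  rs <- local({
    set.seed(seed)
    sample.int(n_pool, n_random)
  })
  sims <- t(vapply(
    rs,
    function(i) ensemble_similarities(features[i, ], members, w, idx, channel),
    numeric(nrow(members))
  ))
  raw <- apply(sims, 1L, function(s) sum(s[s >= s_cut]))
  list(raw = raw, sims = sims, sampled = rs)
}

#' Null moments per protein at a given cutoff
#' @param null_sims List over proteins of `list(sims =, size =)` as produced
#'   by the model driver from [sample_random_raw_scores()].
#' @param s_cut Similarity cutoff at which raw scores are formed.
#' @return Data frame `size, mu, sigma` with one row per protein.
#' @export
null_moments <- function(null_sims, s_cut) {
  do.call(rbind, lapply(null_sims, function(ns) {
    raw <- rowSums(ns$sims * (ns$sims >= s_cut))
    data.frame(size = ns$size, mu = mean(raw), sigma = stats::sd(raw))
  }))
}

#' Fit the size-dependent null model by linear regression
#'
#' Ordinary least squares of the per-protein null mean and null standard
#' deviation of random raw scores against ligand-set size:
#' \eqn{y_\mu = \alpha_1 x + \beta_1}, \eqn{y_\sigma = \alpha_2 x + \beta_2}.
#'
#' @param sizes Ligand-set sizes (one per protein; >= 3 distinct values
#'   required unless exactly two proteins are supplied).
#' @param mus,sigmas Per-protein null means and standard deviations.
#' @param channel Channel tag stored for bookkeeping.
#' @param sigma_floor Lower bound applied to predicted sigmas downstream.
#' @return An object of class `wes_null` with slopes/intercepts
#'   (`alpha1`, `beta1`, `alpha2`, `beta2`), R-squared diagnostics and the
#'   fitting table.
#' @export
fit_null <- function(sizes, mus, sigmas, channel = "binary",
                     sigma_floor = 1e-6) {
  stopifnot(length(sizes) == length(mus), length(sizes) == length(sigmas))
  if (length(unique(sizes)) < 2L) {
    stop("null regression needs at least two distinct ligand-set sizes")
  }
  fit_mu <- stats::lm(mus ~ sizes)
  fit_sd <- stats::lm(sigmas ~ sizes)
  # summary.lm warns on noise-free (exact-interpolation) inputs; those are
  # legitimate here (R^2 = 1 cases in calibration checks)
  r2 <- function(f) {
    s <- suppressWarnings(summary(f))
    if (is.null(s$r.squared) || is.nan(s$r.squared)) 1 else s$r.squared
  }
  structure(
    list(
      channel = channel,
      alpha1 = unname(stats::coef(fit_mu)[2L]),
      beta1 = unname(stats::coef(fit_mu)[1L]),
      alpha2 = unname(stats::coef(fit_sd)[2L]),
      beta2 = unname(stats::coef(fit_sd)[1L]),
      r2_mu = r2(fit_mu),
      r2_sigma = r2(fit_sd),
      se_mu = suppressWarnings(
        stats::coef(summary(fit_mu))[, "Std. Error"]
      ),
      se_sigma = suppressWarnings(
        stats::coef(summary(fit_sd))[, "Std. Error"]
      ),
      sigma_floor = sigma_floor,
      table = data.frame(size = sizes, mu = mus, sigma = sigmas)
    ),
    class = "wes_null"
  )
}

#' Fit the null model directly from cached null similarity matrices
#' @inheritParams null_moments
#' @inheritParams fit_null
#' @return A `wes_null` object (see [fit_null()]).
#' @export
fit_null_from_sims <- function(null_sims, s_cut, channel = "binary",
                               sigma_floor = 1e-6) {
  mom <- null_moments(null_sims, s_cut)
  fit_null(mom$size, mom$mu, mom$sigma,
    channel = channel,
    sigma_floor = sigma_floor
  )
}

#' @export
print.wes_null <- function(x, ...) {
  cat(sprintf(
    "Null model (%s): mu = %.4g*size + %.4g (R2 %.3f); sigma = %.4g*size + %.4g (R2 %.3f)\n",
    x$channel, x$alpha1, x$beta1, x$r2_mu, x$alpha2, x$beta2, x$r2_sigma
  ))
  invisible(x)
}

#' Convert raw ensemble scores to Z-scores
#'
#' \deqn{Z = \frac{raw - (\alpha_1 n + \beta_1)}
#'                {\max(\alpha_2 n + \beta_2, \sigma_{floor})}}
#' where n is the target's ligand-set size. The denominator is floored so
#' the score is defined even where the sigma regression predicts a
#' non-positive value at small sizes.
#'
#' @param raw Numeric vector of raw scores.
#' @param null A `wes_null` object.
#' @param set_size Ligand-set size(s), recycled against `raw`.
#' @return Numeric vector of Z-scores.
#' @export
z_score <- function(raw, null, set_size) {
  stopifnot(inherits(null, "wes_null"))
  mu <- null$alpha1 * set_size + null$beta1
  sg <- null$alpha2 * set_size + null$beta2
  low <- sg < null$sigma_floor
  if (any(low)) sg[low] <- null$sigma_floor
  (raw - mu) / sg
}

#' Choose the Z-score decision threshold by LOOCV F1
#'
#' Scans all observed Z values (calls are `z > threshold`) and returns the
#' threshold with the highest F1; ties toward the smallest threshold. Used
#' for the single-channel models; the hybrid likelihood threshold is chosen
#' by the same criterion via [choose_theta()].
#'
#' @param z Numeric Z-scores (typically pooled held-out LOOCV scores).
#' @param labels True pair labels.
#' @return List with `threshold`, `f1`, `scan` (see [f1_threshold_scan()]).
#' @export
choose_z_threshold <- function(z, labels) f1_threshold_scan(z, labels)
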