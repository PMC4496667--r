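#' Fit a bivariate Gaussian kernel density to class Z-scores
#'
#' Class-conditional density over the two channel Z-scores (z1, z2),
#' estimated as the mean of Gaussian kernels centred at the training points
#' with a shared full bandwidth matrix H:
#' \deqn{\hat f(x) = \frac{1}{n} \sum_k \phi_H(x - x_k)}
#'
#' Bandwidth rules (d = 2): Scott `H = n^{-2/(d+4)} S`, Silverman
#' `H = (4/(d+2))^{2/(d+4)} n^{-2/(d+4)} S`, with S the sample covariance;
#' or a user-supplied fixed H. A singular covariance triggers a fallback to
#' a diagonal (variance-floored) H with a warning.
#'
#' @param points Numeric n x 2 matrix of class training Z-scores (n >= 2).
#' @param bandwidth_rule `"scott"`, `"silverman"` or `"fixed"`.
#' @param H Bandwidth matrix when `bandwidth_rule = "fixed"`.
#' @param var_floor Variance floor for the degenerate-covariance fallback.
#' @return An object of class `wes_kde` with the training points, `H`, its
#'   Cholesky-derived inverse and normalizing constant, and `n`.
#' @export
fit_kde <- function(points, bandwidth_rule = c("scott", "silverman", "fixed"),
                    H = NULL, var_floor = 1e-8) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be an n x 2 matrix")
  n <- nrow(points)
  if (n < 2L) stop("at least 2 points are required to fit the density")
  if (any(!is.finite(points))) stop("non-finite training points")
  d <- 2L
  if (bandwidth_rule == "fixed") {
    if (is.null(H)) stop("bandwidth_rule = 'fixed' requires H")
  } else {
    S <- stats::cov(points)
    fac <- n^(-2 / (d + 4))
    if (bandwidth_rule == "silverman") fac <- fac * (4 / (d + 2))^(2 / (d + 4))
    H <- fac * S
  }
  H <- (H + t(H)) / 2
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(var_floor) / 10)) {
    warning("singular bandwidth matrix; falling back to diagonal H",
      call. = FALSE
    )
    v <- pmax(apply(points, 2L, stats::var), var_floor)
    fac <- n^(-2 / (d + 4))
    H <- diag(fac * v, 2L)
    ch <- chol(H)
  }
  structure(
    list(
      points = points, H = H, n = n,
      chol = ch,
      log_norm = -log(2 * pi) - sum(log(diag(ch))),
      rule = bandwidth_rule
    ),
    class = "wes_kde"
  )
}

#' Evaluate a fitted class density
#'
#' @param kde A `wes_kde` object.
#' @param x Numeric matrix (m x 2) or length-2 vector of evaluation points.
#' @param exclude Optional integer vector, recycled per evaluation row: the
#'   index of one training point to leave out of the kernel sum for that row
#'   (exact leave-one-out evaluation; `NA` = exclude nothing).
#' @return Numeric vector of density values (non-negative).
#' @export
kde_density <- function(kde, x, exclude = NULL) {
  stopifnot(inherits(kde, "wes_kde"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  m <- nrow(x)
  if (!is.null(exclude)) exclude <- rep_len(exclude, m)
  # kernel matrix: phi_H(x_i - p_k) for all eval rows i, training rows k
  p <- kde$points
  # solve via Cholesky: quadratic form (x-p)' H^{-1} (x-p)
  Li <- backsolve(kde$chol, diag(2L)) # H^{-1/2} (upper-tri inverse)
  xe <- x %*% Li
  pe <- p %*% Li
  d2 <- outer(rowSums(xe^2), rowSums(pe^2), `+`) - 2 * tcrossprod(xe, pe)
  kern <- exp(kde$log_norm - pmax(d2, 0) / 2)
  out <- numeric(m)
  for (i in seq_len(m)) {
    ki <- kern[i, ]
    if (!is.null(exclude) && !is.na(exclude[i])) {
      ki <- ki[-exclude[i]]
    }
    out[i] <- mean(ki)
  }
  out
}

#' Bayesian likelihood of binding from the two channel Z-scores
#'
#' Posterior probability of the binder class at (z1, z2) under Bayes' rule
#' with class-conditional KDE densities and class priors:
#' \deqn{L = \frac{\pi_+ \hat f_+(z)}{\pi_+ \hat f_+(z) + \pi_- \hat f_-(z)}}
#' Where both densities vanish numerically, the prior for the binder class
#' is returned with a warning.
#'
#' @param z1,z2 Channel Z-scores (vectors of equal length).
#' @param density_pos,density_neg Fitted `wes_kde` class densities.
#' @param priors Length-2 vector `c(binder, nonbinder)`; normalized
#'   internally. Default: equal priors.
#' @param exclude_pos,exclude_neg Optional per-point leave-one-out indices
#'   forwarded to [kde_density()].
#' @return Likelihood values in `[0, 1]`.
#' @export
likelihood <- function(z1, z2, density_pos, density_neg,
                       priors = c(0.5, 0.5),
                       exclude_pos = NULL, exclude_neg = NULL) {
  stopifnot(length(z1) == length(z2), length(priors) == 2L, all(priors > 0))
  priors <- priors / sum(priors)
  x <- cbind(z1, z2)
  fp <- kde_density(density_pos, x, exclude = exclude_pos)
  fn <- kde_density(density_neg, x, exclude = exclude_neg)
  num <- priors[1L] * fp
  den <- num + priors[2L] * fn
  out <- numeric(length(den))
  zero <- den <= 0 | !is.finite(den)
  if (any(zero)) {
    warning("both class densities ~0 at some points; returning the prior",
      call. = FALSE
    )
    out[zero] <- priors[1L]
  }
  out[!zero] <- num[!zero] / den[!zero]
  pmin(pmax(out, 0), 1)
}

#' Choose the likelihood decision threshold
#'
#' Same highest-F1 scan as the Z-score threshold, applied to likelihood
#' values (calls are `L > theta`).
#'
#' @param L Likelihood values (typically pooled held-out LOOCV values).
#' @param labels True pair labels.
#' @return List with `threshold`, `f1`, `scan`.
#' @export
choose_theta <- function(L, labels) {
  if (length(unique(L)) == 1L) {
    warning("constant likelihood; threshold degenerate", call. = FALSE)
    return(list(
      threshold = L[1L], f1 = NA_real_,
      scan = data.frame(threshold = L[1L], f1 = NA_real_)
    ))
  }
  f1_threshold_scan(L, labels)
}
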