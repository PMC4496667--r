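#' Model configuration
#'
#' Every tunable of the weighted-ensemble pipeline in one place.
#'
#' @param channels Feature channels to train: `"binary"`, `"continuous"`,
#'   or both (the hybrid model; default).
#' @param q_threshold Significance cutoff for feature weights (default
#'   0.05).
#' @param m_binary,m_continuous Per-channel caps on retained features; the
#'   count actually used is `min(cap, significant features)`.
#' @param n_random Random-ligand draw size for null calibration (default
#'   50).
#' @param sigma_floor Lower bound on the null standard deviation.
#' @param grid Similarity-cutoff scan grid (default 0.01..0.99 step 0.01).
#' @param bandwidth_rule KDE bandwidth rule for the hybrid densities.
#' @param priors `"empirical"` (training class frequencies) or `"uniform"`.
#' @param seed Master seed; all draws derive from it via [split_seed()].
#' @return A `wes_config` list.
#' @export
wes_config <- function(channels = c("binary", "continuous"),
                       q_threshold = 0.05, m_binary = 256L,
                       m_continuous = 64L, n_random = 50L,
                       sigma_floor = 1e-6, grid = s_cut_grid(),
                       bandwidth_rule = "scott",
                       priors = c("empirical", "uniform"), seed = 1L) {
  channels <- match.arg(channels, c("binary", "continuous"),
    several.ok = TRUE
  )
  priors <- match.arg(priors)
  structure(
    list(
      channels = channels, q_threshold = q_threshold,
      m_binary = as.integer(m_binary), m_continuous = as.integer(m_continuous),
      n_random = as.integer(n_random), sigma_floor = sigma_floor,
      grid = grid, bandwidth_rule = bandwidth_rule, priors = priors,
      seed = as.integer(seed)
    ),
    class = "wes_config"
  )
}

# features for one channel from the library matrices (internal)
channel_matrix <- function(fp, desc, channel) {
  if (channel == "binary") fp else desc
}

# Build one protein's trained ensemble state (internal).
# Returns per-channel weights/selection plus the members' selected columns.
build_ensemble <- function(protein_id, fp, desc, set_ids, cfg, stats = NULL) {
  set_rows <- match(set_ids, rownames(fp))
  if (anyNA(set_rows)) {
    stop(sprintf(
      "ligand(s) of %s missing from feature matrices", protein_id
    ))
  }
  ww <- weight_ensemble(fp, desc, set_rows,
    q_threshold = cfg$q_threshold,
    m_binary = cfg$m_binary, m_continuous = cfg$m_continuous,
    stats = stats
  )
  channels <- list()
  for (ch in cfg$channels) {
    w <- ww[[ch]]
    feats <- channel_matrix(fp, desc, ch)
    channels[[ch]] <- list(
      weights = w$weights, q = w$q, selected = w$selected,
      members = feats[set_rows, w$selected, drop = FALSE]
    )
  }
  list(
    protein_id = protein_id, ligand_ids = set_ids, size = length(set_ids),
    channels = channels
  )
}

# similarities of a batch of query rows against a trained ensemble:
# returns queries x members matrix (internal vectorized core)
ensemble_queries_sims <- function(ens, channel, queries) {
  ch <- ens$channels[[channel]]
  nq <- nrow(queries)
  if (length(ch$selected) == 0L) {
    return(matrix(0, nq, ens$size))
  }
  w <- ch$weights[ch$selected]
  q <- queries[, ch$selected, drop = FALSE]
  m <- ch$members
  if (channel == "binary") {
    mw <- sweep(m, 2L, w, `*`)
    num <- tcrossprod(q, mw) # nq x k: sum_j w_j q_j m_j
    den <- outer(as.numeric(q %*% w), as.numeric(m %*% w), `+`) - num
    s <- num / den
    s[den == 0] <- 0
  } else {
    qw <- sweep(q, 2L, w, `*`)
    mw <- sweep(m, 2L, w, `*`)
    num <- tcrossprod(qw, mw)
    den <- outer(sqrt(rowSums(qw^2)), sqrt(rowSums(mw^2)))
    s <- pmin(pmax(num / den, 0), 1)
    s[den == 0] <- 0
  }
  s
}

# single-query convenience wrapper
ensemble_query_sims <- function(ens, channel, query) {
  as.numeric(ensemble_queries_sims(ens, channel, matrix(query, nrow = 1L)))
}

# null similarity cache for one ensemble/channel (internal)
null_sims_for <- function(ens, channel, fp, desc, cfg) {
  feats <- channel_matrix(fp, desc, channel)
  n_pool <- nrow(feats)
  seed <- split_seed(cfg$seed, paste("null", channel, ens$protein_id))
  rs <- local({
    set.seed(seed)
    sample.int(n_pool, cfg$n_random)
  })
  sims <- ensemble_queries_sims(ens, channel, feats[rs, , drop = FALSE])
  list(sims = sims, size = ens$size, sampled = rs, seed = seed)
}

#' Fit the weighted ensemble similarity model
#'
#' Runs the full training cascade on a filtered interaction data set:
#' per-protein feature weighting and selection (both channels), the global
#' similarity-cutoff scan by ROC AUC, null-model calibration (random-ligand
#' raw scores, size regressions), Z-scores for the labeled pairs, the
#' class-conditional KDE pair with class priors, and the F1-optimal decision
#' thresholds. Deterministic given (inputs, config, seed).
#'
#' @param fp Binary fingerprint matrix for the full ligand library (row
#'   names = ligand ids).
#' @param desc Standardized continuous descriptor matrix (same row order
#'   not required, but same ids).
#' @param sets Named list: protein id -> character vector of member ligand
#'   ids.
#' @param pairs Data frame of labeled training pairs (`protein_id`,
#'   `ligand_id`, `label` 0/1).
#' @param config A [wes_config()].
#' @param s_cut Optional named list/vector fixing the per-channel similarity
#'   cutoff instead of scanning (used by leave-one-out refits, where the
#'   cutoff is a hyperparameter chosen once on the full data).
#' @return A `wes_model` object.
#' @export
wes_fit <- function(fp, desc, sets, pairs, config = wes_config(),
                    s_cut = NULL) {
  stopifnot(inherits(config, "wes_config"))
  if (length(config$channels) > 1L && is.null(desc)) {
    stop("hybrid model requires both feature channels")
  }
  if (!all(pairs$label %in% c(0L, 1L))) stop("labels must be 0/1")
  if (is.null(rownames(fp))) stop("fp needs ligand ids as row names")
  if (!is.null(desc) && is.null(rownames(desc))) {
    stop("desc needs ligand ids as row names")
  }

  stats <- library_feature_stats(fp, desc)
  ensembles <- lapply(
    names(sets),
    function(p) build_ensemble(p, fp, desc, sets[[p]], config, stats = stats)
  )
  names(ensembles) <- names(sets)

  labels <- as.logical(pairs$label)
  pair_prot <- match(pairs$protein_id, names(ensembles))
  if (anyNA(pair_prot)) stop("pair references unknown protein id")
  pair_sizes <- vapply(ensembles[pair_prot], `[[`, 0L, "size")
  # a labeled pair whose ligand is itself a set member must not score
  # against itself: drop the self-similarity and use the reduced set size
  pair_self <- vapply(seq_len(nrow(pairs)), function(i) {
    match(pairs$ligand_id[i], sets[[pair_prot[i]]], nomatch = NA_integer_)
  }, integer(1))
  pair_sizes <- pair_sizes - !is.na(pair_self)

  channel_fit <- list()
  z_mat <- matrix(NA_real_, nrow(pairs), length(config$channels),
    dimnames = list(NULL, config$channels)
  )
  for (ch in config$channels) {
    feats <- channel_matrix(fp, desc, ch)
    pair_sims <- vector("list", nrow(pairs))
    for (pi in seq_along(ensembles)) {
      rows <- which(pair_prot == pi)
      if (!length(rows)) next
      sm <- ensemble_queries_sims(
        ensembles[[pi]], ch,
        feats[pairs$ligand_id[rows], , drop = FALSE]
      )
      for (r in seq_along(rows)) {
        s <- sm[r, ]
        if (!is.na(pair_self[rows[r]])) s <- s[-pair_self[rows[r]]]
        pair_sims[[rows[r]]] <- s
      }
    }
    null_sims <- lapply(ensembles, null_sims_for,
      channel = ch, fp = fp,
      desc = desc, cfg = config
    )
    if (is.null(s_cut) || is.null(s_cut[[ch]])) {
      scan <- scan_s_cut(pair_sims, pair_sizes, labels, null_sims,
        grid = config$grid, sigma_floor = config$sigma_floor
      )
      sc <- scan$s_cut
      profile <- scan$profile
    } else {
      sc <- s_cut[[ch]]
      profile <- NULL
    }
    null <- fit_null_from_sims(null_sims, sc,
      channel = ch,
      sigma_floor = config$sigma_floor
    )
    raw <- vapply(pair_sims, function(s) sum(s[s >= sc]), numeric(1))
    z <- z_score(raw, null, pair_sizes)
    # an ensemble with no selected features has a null degenerate at
    # exactly zero: the model abstains with Z = 0 rather than inheriting
    # the pooled regression's prediction for its size
    no_feat <- vapply(
      ensembles, function(e) length(e$channels[[ch]]$selected) == 0L,
      logical(1)
    )
    z[no_feat[pair_prot]] <- 0
    thr <- choose_z_threshold(z, labels)
    z_mat[, ch] <- z
    channel_fit[[ch]] <- list(
      s_cut = sc, null = null, scan_profile = profile,
      z_threshold = thr$threshold, z_f1 = thr$f1,
      null_seeds = vapply(null_sims, `[[`, 0L, "seed")
    )
  }

  hybrid <- NULL
  if (length(config$channels) == 2L) {
    pts <- z_mat[, c("binary", "continuous"), drop = FALSE]
    priors <- if (config$priors == "empirical") {
      c(mean(labels), mean(!labels))
    } else {
      c(0.5, 0.5)
    }
    # pairs whose target ensemble abstained on every channel carry no
    # evidence: their likelihood is the class prior and they are kept out
    # of the class-conditional densities
    abst <- vapply(config$channels, function(ch) {
      no_feat <- vapply(
        ensembles, function(e) length(e$channels[[ch]]$selected) == 0L,
        logical(1)
      )
      no_feat[pair_prot]
    }, logical(nrow(pairs)))
    use <- rowSums(!abst) > 0
    L <- rep(priors[1L], nrow(pts))
    kde_pos <- NULL
    kde_neg <- NULL
    if (sum(labels & use) >= 2L && sum(!labels & use) >= 2L) {
      kde_pos <- fit_kde(pts[labels & use, , drop = FALSE],
        config$bandwidth_rule)
      kde_neg <- fit_kde(pts[!labels & use, , drop = FALSE],
        config$bandwidth_rule)
      L[use] <- likelihood(
        pts[use, 1L], pts[use, 2L], kde_pos, kde_neg, priors
      )
    } else if (any(!use)) {
      warning("too few informative pairs to fit class densities; ",
        "likelihood equals the prior everywhere",
        call. = FALSE
      )
    }
    th <- suppressWarnings(choose_theta(L, labels))
    hybrid <- list(
      kde_pos = kde_pos, kde_neg = kde_neg, priors = priors,
      theta = th$threshold, theta_f1 = th$f1
    )
  }

  structure(
    list(
      ensembles = ensembles, channels = channel_fit, hybrid = hybrid,
      config = config,
      training = list(
        pairs = pairs, z = z_mat,
        n_ligands = nrow(fp)
      ),
      provenance = list(
        format_version = 1L, seed = config$seed,
        r_version = as.character(getRversion()),
        created = "wesim"
      )
    ),
    class = "wes_model"
  )
}

#' @export
print.wes_model <- function(x, ...) {
  cat(sprintf(
    "WES model: %d protein ensembles, channels: %s\n",
    length(x$ensembles), paste(x$config$channels, collapse = " + ")
  ))
  for (ch in names(x$channels)) {
    cat(sprintf(
      "  %s: s_cut = %.2f, z threshold = %.3f\n", ch,
      x$channels[[ch]]$s_cut, x$channels[[ch]]$z_threshold
    ))
  }
  if (!is.null(x$hybrid)) {
    cat(sprintf("  hybrid: theta = %.4f\n", x$hybrid$theta))
  }
  invisible(x)
}

#' Predict drug-target interactions with a fitted model
#'
#' For every (query molecule, target) combination: per-channel raw scores
#' and Z-scores, the hybrid Bayesian likelihood (when both channels are
#' trained), and the binary binding call — likelihood above theta for the
#' hybrid model, Z above the channel threshold for single-channel models.
#'
#' @param object A `wes_model`.
#' @param fp,desc Query feature matrices (row names = query ids; `desc` on
#'   the training standardization scale). `desc` may be `NULL` for
#'   binary-only models.
#' @param targets Optional character vector restricting the target set;
#'   unknown ids are an error listing the valid ones. An empty vector gives
#'   an empty result.
#' @param ... Unused.
#' @return Data frame: `ligand_id, protein_id`, per-channel `raw_*`/`z_*`,
#'   `likelihood` (NA for single-channel models), `call`; one row per
#'   query-target combination, ranked within each query.
#' @export
predict.wes_model <- function(object, fp, desc = NULL, targets = NULL, ...) {
  model <- object
  if (is.null(targets)) targets <- names(model$ensembles)
  if (length(targets) == 0L) {
    return(data.frame(
      ligand_id = character(0), protein_id = character(0)
    ))
  }
  bad <- setdiff(targets, names(model$ensembles))
  if (length(bad)) {
    stop(sprintf(
      "unknown target id(s): %s. Valid ids: %s",
      paste(bad, collapse = ", "),
      paste(names(model$ensembles), collapse = ", ")
    ))
  }
  qids <- rownames(fp)
  if (is.null(qids)) stop("query fp needs row names")
  out <- list()
  r <- 0L
  for (q in qids) {
    for (tg in targets) {
      ens <- model$ensembles[[tg]]
      row <- list(ligand_id = q, protein_id = tg)
      for (ch in model$config$channels) {
        feats <- if (ch == "binary") fp[q, ] else desc[q, ]
        sims <- ensemble_query_sims(ens, ch, feats)
        chf <- model$channels[[ch]]
        rs <- raw_score(sims, chf$s_cut)
        z <- if (length(ens$channels[[ch]]$selected) == 0L) {
          0 # featureless ensemble: degenerate null, model abstains
        } else {
          z_score(rs$value, chf$null, ens$size)
        }
        row[[paste0("raw_", ch)]] <- rs$value
        row[[paste0("z_", ch)]] <- z
      }
      r <- r + 1L
      out[[r]] <- row
    }
  }
  res <- do.call(rbind, lapply(out, function(x) {
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
  if (!is.null(model$hybrid)) {
    abst <- vapply(seq_len(nrow(res)), function(i) {
      ens <- model$ensembles[[res$protein_id[i]]]
      all(vapply(
        model$config$channels,
        function(ch) length(ens$channels[[ch]]$selected) == 0L, logical(1)
      ))
    }, logical(1))
    L <- rep(model$hybrid$priors[1L], nrow(res))
    if (!is.null(model$hybrid$kde_pos) && any(!abst)) {
      L[!abst] <- likelihood(
        res$z_binary[!abst], res$z_continuous[!abst],
        model$hybrid$kde_pos, model$hybrid$kde_neg, model$hybrid$priors
      )
    }
    res$likelihood <- L
    res$call <- res$likelihood > model$hybrid$theta
    ord_score <- res$likelihood
  } else {
    ch <- model$config$channels[1L]
    res$likelihood <- NA_real_
    res$call <- res[[paste0("z_", ch)]] > model$channels[[ch]]$z_threshold
    ord_score <- res[[paste0("z_", ch)]]
  }
  res[order(res$ligand_id, -ord_score), , drop = FALSE]
}

# ---- serialization ----------------------------------------------------

#' Save / load a fitted model
#'
#' Version-stamped JSON container; numeric arrays are written with 17
#' significant digits so that a save/load round trip reproduces predictions
#' bit for bit. Loading refuses containers with a different format version.
#'
#' @param model A `wes_model`.
#' @param path Destination / source file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `wes_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wes_model"))
  ser_kde <- function(k) {
    if (is.null(k)) {
      return(NULL)
    }
    list(points = k$points, H = k$H, rule = k$rule)
  }
  payload <- list(
    format_version = model$provenance$format_version,
    config = unclass(model$config),
    provenance = model$provenance,
    ensembles = lapply(model$ensembles, function(e) {
      list(
        protein_id = e$protein_id, ligand_ids = e$ligand_ids,
        size = e$size,
        channels = lapply(e$channels, function(ch) {
          list(
            weights = ch$weights, q = ch$q, selected = ch$selected,
            members = ch$members
          )
        })
      )
    }),
    channels = lapply(model$channels, function(ch) {
      list(
        s_cut = ch$s_cut, z_threshold = ch$z_threshold, z_f1 = ch$z_f1,
        null = list(
          channel = ch$null$channel,
          alpha1 = ch$null$alpha1, beta1 = ch$null$beta1,
          alpha2 = ch$null$alpha2, beta2 = ch$null$beta2,
          r2_mu = ch$null$r2_mu, r2_sigma = ch$null$r2_sigma,
          sigma_floor = ch$null$sigma_floor,
          table = ch$null$table
        ),
        null_seeds = ch$null_seeds
      )
    }),
    hybrid = if (is.null(model$hybrid)) {
      NULL
    } else {
      list(
        kde_pos = ser_kde(model$hybrid$kde_pos),
        kde_neg = ser_kde(model$hybrid$kde_neg),
        priors = model$hybrid$priors, theta = model$hybrid$theta,
        theta_f1 = model$hybrid$theta_f1
      )
    }
  )
  json <- jsonlite::toJSON(payload,
    digits = I(17), auto_unbox = TRUE,
    null = "null", dataframe = "columns"
  )
  writeLines(json, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path))
  payload <- tryCatch(
    jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE),
    error = function(e) stop(sprintf("cannot parse model file: %s", e$message))
  )
  if (is.null(payload$format_version)) {
    stop("not a wesim model file (no format version)")
  }
  if (payload$format_version != 1L) {
    stop(sprintf(
      "unsupported model format version %s (this build reads version 1)",
      payload$format_version
    ))
  }
  cfg <- payload$config
  config <- wes_config(
    channels = cfg$channels, q_threshold = cfg$q_threshold,
    m_binary = cfg$m_binary, m_continuous = cfg$m_continuous,
    n_random = cfg$n_random, sigma_floor = cfg$sigma_floor,
    grid = cfg$grid, bandwidth_rule = cfg$bandwidth_rule,
    priors = cfg$priors, seed = cfg$seed
  )
  ensembles <- lapply(payload$ensembles, function(e) {
    chans <- lapply(e$channels, function(ch) {
      members <- as.matrix(ch$members)
      if (length(ch$selected) == 0L) {
        members <- matrix(0, nrow = e$size, ncol = 0L)
      }
      list(
        weights = as.numeric(ch$weights), q = as.numeric(ch$q),
        selected = as.integer(ch$selected), members = members
      )
    })
    list(
      protein_id = e$protein_id, ligand_ids = e$ligand_ids,
      size = as.integer(e$size), channels = chans
    )
  })
  channels <- lapply(payload$channels, function(ch) {
    nl <- ch$null
    null <- structure(
      list(
        channel = nl$channel, alpha1 = nl$alpha1, beta1 = nl$beta1,
        alpha2 = nl$alpha2, beta2 = nl$beta2, r2_mu = nl$r2_mu,
        r2_sigma = nl$r2_sigma, sigma_floor = nl$sigma_floor,
        table = as.data.frame(nl$table)
      ),
      class = "wes_null"
    )
    list(
      s_cut = ch$s_cut, null = null, scan_profile = NULL,
      z_threshold = ch$z_threshold, z_f1 = ch$z_f1,
      null_seeds = ch$null_seeds
    )
  })
  hybrid <- NULL
  if (!is.null(payload$hybrid)) {
    mk_kde <- function(k) {
      if (is.null(k)) {
        return(NULL)
      }
      fit_kde(as.matrix(k$points), "fixed", H = as.matrix(k$H))
    }
    hybrid <- list(
      kde_pos = mk_kde(payload$hybrid$kde_pos),
      kde_neg = mk_kde(payload$hybrid$kde_neg),
      priors = as.numeric(payload$hybrid$priors),
      theta = payload$hybrid$theta, theta_f1 = payload$hybrid$theta_f1
    )
  }
  structure(
    list(
      ensembles = ensembles, channels = channels, hybrid = hybrid,
      config = config, training = NULL, provenance = payload$provenance
    ),
    class = "wes_model"
  )
}
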