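#' Configuration for the synthetic benchmark generator
#'
#' Defines the generative model the weighted-ensemble method assumes: each
#' target protein owns a ligand set whose members express a planted set of
#' signature fingerprint bits at probability `p_on` (background bits at
#' `p_bg`) and whose signature descriptors are shifted by `desc_effect`
#' standard deviations; background molecules carry background statistics
#' only. With `n_clusters >= 2` the signature is split into disjoint
#' per-cluster subsets, creating genuinely multi-chemotype ligand sets for
#' scaffold-hopping experiments. Optional "generic" bits are on with high
#' probability in every molecule (set and background alike), mimicking the
#' ubiquitous substructure bits of hashed fingerprints that inflate plain
#' Tanimoto similarity without carrying target information.
#'
#' @param n_proteins Number of target proteins.
#' @param ligands_per_protein Ligand-set size per target.
#' @param n_background_ligands Background (non-binder) molecules.
#' @param n_bits Fingerprint length B.
#' @param n_desc Continuous descriptor count D.
#' @param n_signature_bits Signature bits per protein (s).
#' @param n_signature_desc Signature descriptors per protein.
#' @param p_on Signature-bit probability within the set's own cluster.
#' @param p_bg Background bit probability (everywhere else).
#' @param desc_effect Mean shift of signature descriptors, in SD units.
#' @param n_clusters Chemotype clusters per ligand set (>= 2 splits the
#'   signature into disjoint per-cluster subsets).
#' @param n_generic_bits Bits on with probability `p_generic` in all
#'   molecules (default 0: none).
#' @param p_generic On-probability of generic bits.
#' @param size_jitter Ligand-set sizes are drawn uniformly from
#'   `ligands_per_protein` plus/minus this amount (floored at 5, the
#'   post-filter minimum). The size variation is what the null model's
#'   moment-versus-size regressions are fitted on; `0` gives identical
#'   sizes, which makes those regressions singular and is rejected by
#'   [wes_fit()].
#' @param neg_ratio Negative:positive labeled-pair ratio (default 1,
#'   balanced).
#' @param seed Master seed; every stream is derived from it via
#'   [split_seed()].
#' @return A `wes_benchmark_config` list.
#' @export
wes_benchmark_config <- function(n_proteins = 50L, ligands_per_protein = 20L,
                                 n_background_ligands = 500L, n_bits = 1024L,
                                 n_desc = 128L, n_signature_bits = 30L,
                                 n_signature_desc = 10L, p_on = 0.6,
                                 p_bg = 0.05, desc_effect = 1.5,
                                 n_clusters = 1L, n_generic_bits = 0L,
                                 p_generic = 0.85, size_jitter = 5L,
                                 neg_ratio = 1L, seed = 7L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    ligands_per_protein = as.integer(ligands_per_protein),
    n_background_ligands = as.integer(n_background_ligands),
    n_bits = as.integer(n_bits), n_desc = as.integer(n_desc),
    n_signature_bits = as.integer(n_signature_bits),
    n_signature_desc = as.integer(n_signature_desc),
    p_on = p_on, p_bg = p_bg, desc_effect = desc_effect,
    n_clusters = as.integer(n_clusters),
    n_generic_bits = as.integer(n_generic_bits), p_generic = p_generic,
    size_jitter = as.integer(size_jitter),
    neg_ratio = as.integer(neg_ratio), seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_proteins > 0, cfg$ligands_per_protein > 0,
    cfg$n_background_ligands > 0, cfg$n_bits > 0, cfg$n_desc > 0,
    cfg$n_signature_bits + cfg$n_generic_bits <= cfg$n_bits,
    cfg$n_signature_desc <= cfg$n_desc,
    cfg$p_bg >= 0, cfg$p_on <= 1, cfg$p_bg <= cfg$p_on,
    cfg$n_clusters >= 1, cfg$neg_ratio >= 1
  )
  class(cfg) <- "wes_benchmark_config"
  cfg
}

# Draw feature rows for molecules of one protein/cluster (internal).
# sig_bits may be integer(0) (background molecule); sig_desc likewise.
draw_molecules <- function(n, cfg, sig_bits, sig_desc, generic_bits) {
  fp <- matrix(stats::rbinom(n * cfg$n_bits, 1L, cfg$p_bg),
    nrow = n, ncol = cfg$n_bits
  )
  if (length(sig_bits)) {
    fp[, sig_bits] <- stats::rbinom(n * length(sig_bits), 1L, cfg$p_on)
  }
  if (length(generic_bits)) {
    fp[, generic_bits] <- stats::rbinom(
      n * length(generic_bits), 1L,
      cfg$p_generic
    )
  }
  desc <- matrix(stats::rnorm(n * cfg$n_desc), nrow = n, ncol = cfg$n_desc)
  if (length(sig_desc)) {
    desc[, sig_desc] <- desc[, sig_desc] + cfg$desc_effect
  }
  list(fp = fp, desc = desc)
}

#' Generate a synthetic target-fishing benchmark
#'
#' Produces the full offline stand-in for a protein-ligand interaction
#' corpus: both feature channels for every molecule, the protein-to-ligand
#' set map, balanced (or `neg_ratio`-weighted) labeled pairs, and the
#' planted ground truth (per-protein signature features and cluster
#' assignments) against which feature-weight recovery can be checked.
#'
#' @param cfg A [wes_benchmark_config()].
#' @return A `wes_benchmark` list with elements `fp` (molecules x bits,
#'   0/1), `desc` (molecules x descriptors), `sets` (named list: protein ->
#'   member ligand ids), `pairs` (data frame `protein_id, ligand_id, label`),
#'   `signatures` (per protein: `bits`, `desc`, `cluster_bits`,
#'   `cluster_desc`, member cluster ids), `generic_bits`, `config`.
#' @export
generate_benchmark <- function(cfg = wes_benchmark_config()) {
  stopifnot(inherits(cfg, "wes_benchmark_config"))
  prot_ids <- sprintf("P%03d", seq_len(cfg$n_proteins))
  bg_ids <- sprintf("B%05d", seq_len(cfg$n_background_ligands))

  # per-protein ligand-set sizes (variation drives the null regressions)
  set.seed(split_seed(cfg$seed, "set-sizes"))
  sizes <- pmax(
    5L,
    cfg$ligands_per_protein +
      sample.int(2L * cfg$size_jitter + 1L, cfg$n_proteins, replace = TRUE) -
      cfg$size_jitter - 1L
  )
  memb_ids <- sprintf("L%05d", seq_len(sum(sizes)))

  # planted signatures (bit/descriptor indices per protein, split by cluster)
  set.seed(split_seed(cfg$seed, "signatures"))
  generic_bits <- if (cfg$n_generic_bits > 0) seq_len(cfg$n_generic_bits) else integer(0)
  candidate_bits <- setdiff(seq_len(cfg$n_bits), generic_bits)
  signatures <- lapply(seq_along(prot_ids), function(pi) {
    bits <- sort(sample(candidate_bits, cfg$n_signature_bits))
    dsc <- sort(sample(cfg$n_desc, cfg$n_signature_desc))
    cl_b <- split(bits, rep_len(seq_len(cfg$n_clusters), length(bits)))
    cl_d <- split(dsc, rep_len(seq_len(cfg$n_clusters), length(dsc)))
    member_cluster <- rep_len(seq_len(cfg$n_clusters), sizes[pi])
    list(
      bits = bits, desc = dsc, cluster_bits = cl_b, cluster_desc = cl_d,
      member_cluster = member_cluster
    )
  })
  names(signatures) <- prot_ids

  # member molecules, protein by protein, cluster-structured
  set.seed(split_seed(cfg$seed, "members"))
  fp <- matrix(0L, nrow = 0, ncol = cfg$n_bits)
  desc <- matrix(0, nrow = 0, ncol = cfg$n_desc)
  sets <- vector("list", cfg$n_proteins)
  names(sets) <- prot_ids
  idx0 <- 0L
  fp_list <- vector("list", cfg$n_proteins)
  desc_list <- vector("list", cfg$n_proteins)
  for (pi in seq_along(prot_ids)) {
    sg <- signatures[[pi]]
    rows_fp <- matrix(0L, sizes[pi], cfg$n_bits)
    rows_desc <- matrix(0, sizes[pi], cfg$n_desc)
    for (cl in seq_len(cfg$n_clusters)) {
      members <- which(sg$member_cluster == cl)
      if (!length(members)) next
      mol <- draw_molecules(
        length(members), cfg, sg$cluster_bits[[cl]],
        sg$cluster_desc[[cl]], generic_bits
      )
      rows_fp[members, ] <- mol$fp
      rows_desc[members, ] <- mol$desc
    }
    fp_list[[pi]] <- rows_fp
    desc_list[[pi]] <- rows_desc
    sets[[pi]] <- memb_ids[idx0 + seq_len(sizes[pi])]
    idx0 <- idx0 + sizes[pi]
  }
  set.seed(split_seed(cfg$seed, "background"))
  bg <- draw_molecules(
    cfg$n_background_ligands, cfg, integer(0), integer(0),
    generic_bits
  )
  fp <- do.call(rbind, c(fp_list, list(bg$fp)))
  desc <- do.call(rbind, c(desc_list, list(bg$desc)))
  rownames(fp) <- rownames(desc) <- c(memb_ids, bg_ids)

  # labeled pairs: every (member, own protein) positive; negatives sampled
  # uniformly from (background molecule, protein) pairs, no duplicates
  positives <- data.frame(
    protein_id = rep(prot_ids, times = sizes),
    ligand_id = memb_ids,
    label = 1L,
    stringsAsFactors = FALSE
  )
  n_neg <- nrow(positives) * cfg$neg_ratio
  universe <- cfg$n_background_ligands * cfg$n_proteins
  if (n_neg > universe) stop("background too small for requested negatives")
  set.seed(split_seed(cfg$seed, "negatives"))
  pick <- sample.int(universe, n_neg)
  negatives <- data.frame(
    protein_id = prot_ids[(pick - 1L) %/% cfg$n_background_ligands + 1L],
    ligand_id = bg_ids[(pick - 1L) %% cfg$n_background_ligands + 1L],
    label = 0L,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      fp = fp, desc = desc, sets = sets,
      pairs = rbind(positives, negatives),
      signatures = signatures, generic_bits = generic_bits, config = cfg
    ),
    class = "wes_benchmark"
  )
}

#' @export
print.wes_benchmark <- function(x, ...) {
  cat(sprintf(
    "Synthetic benchmark: %d proteins x %d ligands, %d background molecules, %d labeled pairs (B = %d bits, D = %d descriptors, %d cluster(s))\n",
    x$config$n_proteins, x$config$ligands_per_protein,
    x$config$n_background_ligands, nrow(x$pairs), x$config$n_bits,
    x$config$n_desc, x$config$n_clusters
  ))
  invisible(x)
}

#' Canonical configuration for the scaffold-hopping contrast
#'
#' A two-cluster benchmark calibrated so that the evaluation reproduces the
#' qualitative regime of real target fishing: close analogs retrieve their
#' target at nearest-neighbour Tanimoto (Tc) above 0.6; cluster hoppers —
#' probes from one chemotype cluster expressing the pharmacophore only
#' partially — have max-Tc below 0.4, overlapping the decoy distribution so
#' a plain 1NN screen cannot separate them; and decoys outnumber actives
#' 3:1 as in a screening library. Generic high-frequency bits and a
#' moderate background bit rate provide the Tc dilution; the enriched-bit
#' weighted ensemble score is unaffected by those bits (they are not
#' enriched) and still resolves the hoppers.
#'
#' @param seed Master seed.
#' @return A [wes_benchmark_config()].
#' @export
wes_scaffold_config <- function(seed = 7L) {
  wes_benchmark_config(
    n_proteins = 25L, ligands_per_protein = 16L, n_background_ligands = 300L,
    n_bits = 1024L, n_desc = 64L, n_signature_bits = 30L,
    n_signature_desc = 8L, p_on = 0.9, p_bg = 0.12, desc_effect = 1.5,
    n_clusters = 2L, n_generic_bits = 160L, p_generic = 0.85,
    size_jitter = 4L, seed = seed
  )
}

#' Draw fresh probe molecules for a scaffold-hopping experiment
#'
#' Three probe families against an existing benchmark's proteins:
#' \describe{
#'   \item{analog}{a copy of a randomly chosen set member with a fraction
#'     `mutation` of its bits resampled from the member's own generative
#'     probabilities — a close structural analog (high nearest-neighbour
#'     Tanimoto).}
#'   \item{hopper}{a fresh molecule from one of the protein's clusters
#'     (default: the last cluster) — shares the cluster signature, so the
#'     weighted ensemble score is informative, while its plain Tanimoto to
#'     every individual member stays low when background/generic bits
#'     dominate.}
#'   \item{decoy}{a fresh background molecule paired with the protein — a
#'     true non-binder.}
#' }
#'
#' @param benchmark A `wes_benchmark` (typically with `n_clusters >= 2`).
#' @param n_analog,n_hopper,n_decoy Probes per protein of each family.
#' @param hop_cluster Cluster index probes are drawn from (`NULL` = last).
#' @param hop_expression Fraction of the cluster's signature on-probability
#'   expressed by hopper probes (default 0.6): distant scaffold hoppers
#'   carry the target pharmacophore only partially, which is what makes
#'   their plain Tanimoto to every individual set member sink into the
#'   decoy range while the enriched-feature weighted similarity still
#'   accumulates over the ensemble.
#' @param mutation Per-bit resampling probability for analog probes.
#' @param seed Seed for the probe stream.
#' @return A list with `fp`, `desc` (probe feature matrices), and `pairs`
#'   (data frame `protein_id, ligand_id, label, family`).
#' @export
generate_scaffold_probes <- function(benchmark, n_analog = 2L, n_hopper = 3L,
                                     n_decoy = 15L, hop_cluster = NULL,
                                     hop_expression = 0.75, mutation = 0.08,
                                     seed = 11L) {
  stopifnot(inherits(benchmark, "wes_benchmark"))
  cfg <- benchmark$config
  if (is.null(hop_cluster)) hop_cluster <- cfg$n_clusters
  stopifnot(hop_cluster >= 1, hop_cluster <= cfg$n_clusters)
  generic <- benchmark$generic_bits
  set.seed(split_seed(seed, "scaffold-probes"))
  fp_rows <- list()
  desc_rows <- list()
  pairs <- list()
  k <- 0L
  for (p in names(benchmark$sets)) {
    sg <- benchmark$signatures[[p]]
    # analogs: perturbed copies of random members
    if (n_analog > 0) {
      pick <- sample(benchmark$sets[[p]], n_analog, replace = TRUE)
      for (lid in pick) {
        v <- benchmark$fp[lid, ]
        cl <- sg$member_cluster[match(lid, benchmark$sets[[p]])]
        probs <- rep(cfg$p_bg, cfg$n_bits)
        probs[sg$cluster_bits[[cl]]] <- cfg$p_on
        if (length(generic)) probs[generic] <- cfg$p_generic
        flip <- stats::runif(cfg$n_bits) < mutation
        v[flip] <- stats::rbinom(sum(flip), 1L, probs[flip])
        d <- benchmark$desc[lid, ] + stats::rnorm(cfg$n_desc, sd = 0.2)
        k <- k + 1L
        fp_rows[[k]] <- v
        desc_rows[[k]] <- d
        pairs[[k]] <- data.frame(
          protein_id = p, ligand_id = sprintf("Q%05d", k),
          label = 1L, family = "analog", stringsAsFactors = FALSE
        )
      }
    }
    if (n_hopper > 0) {
      hop_cfg <- cfg
      hop_cfg$p_on <- cfg$p_bg + hop_expression * (cfg$p_on - cfg$p_bg)
      mol <- draw_molecules(
        n_hopper, hop_cfg, sg$cluster_bits[[hop_cluster]],
        sg$cluster_desc[[hop_cluster]], generic
      )
      for (i in seq_len(n_hopper)) {
        k <- k + 1L
        fp_rows[[k]] <- mol$fp[i, ]
        desc_rows[[k]] <- mol$desc[i, ]
        pairs[[k]] <- data.frame(
          protein_id = p, ligand_id = sprintf("Q%05d", k),
          label = 1L, family = "hopper", stringsAsFactors = FALSE
        )
      }
    }
    if (n_decoy > 0) {
      mol <- draw_molecules(n_decoy, cfg, integer(0), integer(0), generic)
      for (i in seq_len(n_decoy)) {
        k <- k + 1L
        fp_rows[[k]] <- mol$fp[i, ]
        desc_rows[[k]] <- mol$desc[i, ]
        pairs[[k]] <- data.frame(
          protein_id = p, ligand_id = sprintf("Q%05d", k),
          label = 0L, family = "decoy", stringsAsFactors = FALSE
        )
      }
    }
  }
  fp <- do.call(rbind, fp_rows)
  desc <- do.call(rbind, desc_rows)
  pairs <- do.call(rbind, pairs)
  rownames(fp) <- rownames(desc) <- pairs$ligand_id
  list(fp = fp, desc = desc, pairs = pairs)
}

#' Deterministic fixture exercising all five interaction-filter rules
#'
#' A hand-crafted toy interaction table in which each of the five
#' positive-set filtering rules removes at least one entity:
#' \enumerate{
#'   \item an exact duplicate measurement row `(P1, A1, Ki 0.1)`;
#'   \item `(P1, A6)` with mean affinity (5 + 20)/2 = 12.5 uM > 10 uM, and
#'     `(P3, C4)` with no usable affinity;
#'   \item protein `P4` shares 3 of its 4 ligands (75% > 60%) with the
#'     larger set of `P1` and is expunged;
#'   \item within `P1`, ligands `A4` and `A5` have Tanimoto 0.8 > 0.75, so
#'     the greedy pruning removes `A4` (tie broken by ascending id);
#'   \item `P3` retains fewer than 5 ligands and is dropped.
#' }
#' The documented survivor set is `P1 x {A1, A2, A3, A5, A7}` and
#' `P2 x {B1..B5}`.
#'
#' @return A list with `interactions` (data frame `protein_id, ligand_id,
#'   affinity_type, affinity_uM`), `fp` (binary fingerprints of all
#'   ligands), and `expected_survivors` (data frame `protein_id,
#'   ligand_id`).
#' @export
make_filter_fixture <- function() {
  rows <- list(
    c("P1", "A1", "Ki", 0.1), c("P1", "A1", "Ki", 0.1), # rule 1 duplicate
    c("P1", "A2", "Ki", 0.5), c("P1", "A3", "IC50", 1.0),
    c("P1", "A4", "Ki", 2.0), c("P1", "A5", "Ki", 2.0),
    c("P1", "A6", "Ki", 5.0), c("P1", "A6", "IC50", 20.0), # rule 2: mean 12.5
    c("P1", "A7", "IC50", 0.3),
    c("P2", "B1", "Ki", 0.2), c("P2", "B2", "Ki", 0.2),
    c("P2", "B3", "IC50", 1.5), c("P2", "B4", "Ki", 3.0),
    c("P2", "B5", "IC50", 9.0),
    c("P3", "C1", "Ki", 0.1), c("P3", "C2", "Ki", 0.2),
    c("P3", "C3", "Ki", 0.3), c("P3", "C4", NA, NA), # rule 2: no affinity
    c("P4", "A1", "Ki", 0.1), c("P4", "A2", "Ki", 0.2), # rule 3: 3/4 shared
    c("P4", "A3", "Ki", 0.3), c("P4", "D1", "Ki", 0.4)
  )
  interactions <- data.frame(
    protein_id = vapply(rows, `[`, "", 1L),
    ligand_id = vapply(rows, `[`, "", 2L),
    affinity_type = vapply(rows, `[`, "", 3L),
    affinity_uM = as.numeric(vapply(rows, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  lig <- c(
    "A1", "A2", "A3", "A4", "A5", "A6", "A7",
    "B1", "B2", "B3", "B4", "B5", "C1", "C2", "C3", "C4", "D1"
  )
  fp <- matrix(0L, nrow = length(lig), ncol = 16, dimnames = list(lig, NULL))
  # orthogonal single-bit fingerprints except A4/A5, built to share 4 of 5
  # on-bits: Tc = 4/6 ... adjust: A4 = bits 1-4, A5 = bits 1-5 -> Tc = 4/5
  for (i in seq_along(lig)) fp[i, ((i - 1L) %% 11L) + 6L] <- 1L
  fp["A4", ] <- 0L
  fp["A5", ] <- 0L
  fp["A4", 1:4] <- 1L
  fp["A5", 1:5] <- 1L
  expected <- data.frame(
    protein_id = c(rep("P1", 5L), rep("P2", 5L)),
    ligand_id = c("A1", "A2", "A3", "A5", "A7", paste0("B", 1:5)),
    stringsAsFactors = FALSE
  )
  list(interactions = interactions, fp = fp, expected_survivors = expected)
}
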