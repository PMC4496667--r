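#' Read a protein-ligand interaction table
#'
#' Tab-separated text with columns `protein_id`, `ligand_id`,
#' `affinity_type` (`Ki` or `IC50`) and `affinity_uM` (micromolar), one
#' measurement per row; a pair may appear on several rows (e.g. both a Ki
#' and an IC50 measurement). Compatible with BindingDB-style exports after
#' column mapping.
#'
#' @param path File path.
#' @return Data frame of interaction records.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop(sprintf("interaction file not found: %s", path))
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "ligand_id", "affinity_type", "affinity_uM")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  }
  x$affinity_uM <- as.numeric(x$affinity_uM)
  x[need]
}

#' Apply the five positive-set filtering rules
#'
#' In order: (1) drop exact duplicate measurement rows (same protein,
#' ligand, affinity type and value); (2) aggregate each pair's Ki/IC50
#' measurements by arithmetic mean in micromolar and drop pairs with no
#' usable affinity or mean above `affinity_max`; (3) while any protein pair
#' shares more than `overlap_max` of the smaller set's ligands, expunge the
#' smaller-set protein (ties: the lexicographically larger id); (4) within
#' each protein's set, greedily remove ligands until no remaining pair has
#' plain Tanimoto above `tc_max` (most-connected ligand first, ties by
#' ascending id); (5) drop proteins retaining fewer than `min_ligands`
#' ligands. Every removal is recorded in the report.
#'
#' @param records Interaction data frame (see [read_interactions()]).
#' @param fp Binary fingerprint matrix with ligand ids as row names
#'   (required for rule 4; rule 4 is skipped with a warning when `NULL`).
#' @param affinity_max Affinity cutoff in uM (default 10).
#' @param overlap_max Ligand-set overlap threshold (default 0.6, of the
#'   smaller set).
#' @param tc_max Intra-set Tanimoto ceiling (default 0.75).
#' @param min_ligands Minimum surviving ligand-set size (default 5).
#' @return A list with `records` (survivors: one row per pair with the mean
#'   affinity) and `report` (class `wes_filter_report`: per-step before and
#'   after counts plus removal lists).
#' @export
filter_positive_set <- function(records, fp = NULL, affinity_max = 10,
                                overlap_max = 0.6, tc_max = 0.75,
                                min_ligands = 5L) {
  stopifnot(is.data.frame(records))
  report <- list()
  n0 <- nrow(records)

  # (1) exact duplicate measurement rows
  key <- paste(records$protein_id, records$ligand_id, records$affinity_type,
    records$affinity_uM,
    sep = "\r"
  )
  dup <- duplicated(key)
  report$dedupe <- list(
    before = n0, after = sum(!dup),
    removed = records[dup, c("protein_id", "ligand_id")]
  )
  records <- records[!dup, , drop = FALSE]

  # (2) per-pair mean affinity; drop missing or weak (> affinity_max uM)
  pk <- paste(records$protein_id, records$ligand_id, sep = "\r")
  mean_aff <- tapply(records$affinity_uM, pk, function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  pairs <- data.frame(
    protein_id = sub("\r.*", "", names(mean_aff)),
    ligand_id = sub(".*\r", "", names(mean_aff)),
    affinity_uM = as.numeric(mean_aff),
    stringsAsFactors = FALSE
  )
  bad <- is.na(pairs$affinity_uM) | pairs$affinity_uM > affinity_max
  report$affinity <- list(
    before = nrow(pairs), after = sum(!bad),
    removed = pairs[bad, c("protein_id", "ligand_id")]
  )
  pairs <- pairs[!bad, , drop = FALSE]

  # (3) expunge smaller-set proteins overlapping > overlap_max with another
  removed_prot <- character(0)
  repeat {
    sets <- split(pairs$ligand_id, pairs$protein_id)
    if (length(sets) < 2L) break
    ids <- names(sets)
    hit <- NULL
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (i >= j) next
        shared <- length(intersect(sets[[i]], sets[[j]]))
        smaller <- min(length(sets[[i]]), length(sets[[j]]))
        if (shared / smaller > overlap_max) {
          # drop the smaller set; on size ties the larger id
          drop_i <- if (length(sets[[i]]) < length(sets[[j]])) {
            ids[i]
          } else if (length(sets[[j]]) < length(sets[[i]])) {
            ids[j]
          } else {
            max(ids[i], ids[j])
          }
          hit <- drop_i
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    removed_prot <- c(removed_prot, hit)
    pairs <- pairs[pairs$protein_id != hit, , drop = FALSE]
  }
  report$overlap <- list(
    before = report$affinity$after, after = nrow(pairs),
    removed = data.frame(protein_id = removed_prot, stringsAsFactors = FALSE)
  )

  # (4) intra-set Tanimoto pruning (greedy: most >tc_max neighbours first)
  removed_lig <- pairs[0, c("protein_id", "ligand_id")]
  if (is.null(fp)) {
    if (nrow(pairs)) {
      warning("no fingerprints supplied; intra-set Tanimoto rule skipped",
        call. = FALSE
      )
    }
  } else {
    keep_rows <- rep(TRUE, nrow(pairs))
    for (p in unique(pairs$protein_id)) {
      rows <- which(pairs$protein_id == p)
      lig <- pairs$ligand_id[rows]
      miss <- setdiff(lig, rownames(fp))
      if (length(miss)) {
        stop(sprintf(
          "fingerprints missing for ligand(s): %s",
          paste(miss, collapse = ", ")
        ))
      }
      m <- fp[lig, , drop = FALSE]
      inter <- tcrossprod(m)
      ones <- rowSums(m)
      uni <- outer(ones, ones, `+`) - inter
      tc <- ifelse(uni == 0, 0, inter / uni)
      diag(tc) <- 0
      adj <- tc > tc_max
      alive <- rep(TRUE, length(lig))
      repeat {
        deg <- rowSums(adj[alive, alive, drop = FALSE])
        if (!length(deg) || max(deg) == 0) break
        worst <- names(deg)[deg == max(deg)]
        victim <- sort(worst)[1L]
        vi <- match(victim, lig)
        alive[vi] <- FALSE
        removed_lig <- rbind(removed_lig, data.frame(
          protein_id = p, ligand_id = victim, stringsAsFactors = FALSE
        ))
      }
      keep_rows[rows[!alive]] <- FALSE
    }
    pairs <- pairs[keep_rows, , drop = FALSE]
  }
  report$tanimoto <- list(
    before = report$overlap$after, after = nrow(pairs), removed = removed_lig
  )

  # (5) drop proteins with fewer than min_ligands ligands
  sizes <- table(pairs$protein_id)
  small <- names(sizes)[sizes < min_ligands]
  report$min_size <- list(
    before = report$tanimoto$after,
    after = sum(!pairs$protein_id %in% small),
    removed = data.frame(protein_id = small, stringsAsFactors = FALSE)
  )
  pairs <- pairs[!pairs$protein_id %in% small, , drop = FALSE]
  rownames(pairs) <- NULL

  if (nrow(pairs) == 0L) {
    counts <- vapply(report, function(s) s$after, numeric(1))
    stop(sprintf(
      "no interactions survive filtering (after steps: %s)",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")
    ))
  }
  class(report) <- "wes_filter_report"
  list(records = pairs, report = report)
}

#' @export
print.wes_filter_report <- function(x, ...) {
  steps <- c(
    dedupe = "1 duplicate rows", affinity = "2 affinity (mean > cutoff/NA)",
    overlap = "3 protein set overlap", tanimoto = "4 intra-set Tanimoto",
    min_size = "5 minimum set size"
  )
  for (s in names(steps)) {
    cat(sprintf(
      "step %-30s %5d -> %5d (removed %d)\n", steps[[s]],
      x[[s]]$before, x[[s]]$after, x[[s]]$before - x[[s]]$after
    ))
  }
  invisible(x)
}

#' Generate the random negative interaction set
#'
#' Uniformly samples (protein, ligand) pairs from the full cross universe,
#' excluding the positive pairs, without duplicates, matching the positive
#' count (the default) or a requested count.
#'
#' @param positives Data frame with `protein_id`, `ligand_id` (the positive
#'   pairs).
#' @param protein_ids,ligand_ids Universe of ids to sample from.
#' @param n Number of negatives (default: `nrow(positives)`).
#' @param seed Seed for the draw.
#' @return Data frame `protein_id, ligand_id, label = 0`.
#' @export
generate_negative_set <- function(positives, protein_ids, ligand_ids,
                                  n = NULL, seed = 1L) {
  if (is.null(n)) n <- nrow(positives)
  protein_ids <- unique(protein_ids)
  ligand_ids <- unique(ligand_ids)
  universe <- length(protein_ids) * length(ligand_ids)
  pos_key <- paste(positives$protein_id, positives$ligand_id, sep = "\r")
  if (universe - length(unique(pos_key)) < n) {
    stop("not enough non-positive pairs to sample the negative set")
  }
  set.seed(split_seed(seed, "negative-set"))
  chosen <- integer(0)
  while (length(chosen) < n) {
    draw <- sample.int(universe, min(universe, n + length(pos_key)))
    p <- protein_ids[(draw - 1L) %/% length(ligand_ids) + 1L]
    l <- ligand_ids[(draw - 1L) %% length(ligand_ids) + 1L]
    ok <- !(paste(p, l, sep = "\r") %in% pos_key)
    chosen <- unique(c(chosen, draw[ok]))
  }
  chosen <- chosen[seq_len(n)]
  data.frame(
    protein_id = protein_ids[(chosen - 1L) %/% length(ligand_ids) + 1L],
    ligand_id = ligand_ids[(chosen - 1L) %% length(ligand_ids) + 1L],
    label = 0L,
    stringsAsFactors = FALSE
  )
}
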