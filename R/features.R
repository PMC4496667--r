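#' Read ligand structures
#'
#' SMILES TSV (`ligand_id<TAB>smiles`, header optional) or SDF. Parsing
#' requires the ChemmineR/ChemmineOB toolkit; unparseable records are
#' excluded and reported, never silently dropped.
#'
#' @param path File path.
#' @param format `"smiles_tsv"` or `"sdf"`.
#' @param id_tag For SDF input, the SD tag holding the ligand id (`NULL` =
#'   the molecule title line).
#' @return A list of class `wes_ligands`: `ids`, `smiles` (or `sdf`, an
#'   `SDFset`), and `excluded` (data frame of rejected records with
#'   reasons).
#' @export
read_ligands <- function(path, format = c("smiles_tsv", "sdf"), id_tag = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("ligand file not found: %s", path))
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading structures requires the ChemmineR package")
  }
  if (format == "smiles_tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty ligand file")
    parts <- strsplit(lines, "\t")
    if (tolower(trimws(parts[[1L]][1L])) %in% c("ligand_id", "id")) {
      parts <- parts[-1L]
    }
    if (length(parts) == 0L) stop("no ligand records in file")
    ids <- vapply(parts, function(p) trimws(p[1L]), "")
    smi <- vapply(parts, function(p) trimws(p[2L]), "")
    ok <- logical(length(smi))
    for (i in seq_along(smi)) {
      ok[i] <- !is.na(smi[i]) && nzchar(smi[i]) &&
        !inherits(try(ChemmineR::smiles2sdf(smi[i]), silent = TRUE),
          "try-error"
        )
    }
    excluded <- data.frame(
      ligand_id = ids[!ok],
      reason = rep("unparseable SMILES", sum(!ok)), stringsAsFactors = FALSE
    )
    if (!any(ok)) stop("no valid molecules in file")
    if (nrow(excluded)) {
      warning(sprintf("%d unparseable record(s) excluded", nrow(excluded)),
        call. = FALSE
      )
    }
    out <- list(
      ids = ids[ok], smiles = smi[ok], sdf = NULL, excluded = excluded
    )
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdf)
    sdf <- sdf[valid]
    if (length(sdf) == 0L) stop("no valid molecules in file")
    ids <- if (!is.null(id_tag)) {
      vapply(seq_along(sdf), function(i) {
        db <- ChemmineR::datablock(sdf[[i]])
        if (id_tag %in% names(db)) db[[id_tag]] else NA_character_
      }, "")
    } else {
      as.character(ChemmineR::sdfid(sdf))
    }
    excluded <- data.frame(
      ligand_id = sprintf("record_%d", which(!valid)),
      reason = rep("invalid SDF block", sum(!valid)), stringsAsFactors = FALSE
    )
    if (nrow(excluded)) {
      warning(sprintf("%d invalid SDF record(s) excluded", nrow(excluded)),
        call. = FALSE
      )
    }
    out <- list(ids = ids, smiles = NULL, sdf = sdf, excluded = excluded)
  }
  class(out) <- "wes_ligands"
  out
}

#' Compute the binary fingerprint channel
#'
#' 1024-bit hashed fingerprints (OpenBabel FP2 via ChemmineR/ChemmineOB) for
#' parsed ligands, or a pass-through when a precomputed binary matrix is
#' supplied — the synthetic path and external feature matrices bypass the
#' chemistry toolkit entirely.
#'
#' @param ligands A `wes_ligands` object, or a precomputed binary matrix
#'   (rows = ligands) which is validated and returned unchanged.
#' @param n_bits Expected fingerprint length (FP2 yields 1024).
#' @return Binary matrix (ligands x bits) with ligand ids as row names and
#'   attributes `engine`/`engine_version` recording provenance.
#' @export
compute_binary_features <- function(ligands, n_bits = 1024L) {
  if (is.matrix(ligands)) {
    if (!all(ligands %in% c(0L, 1L))) stop("binary matrix must be 0/1")
    return(ligands)
  }
  stopifnot(inherits(ligands, "wes_ligands"))
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
    !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprint computation requires ChemmineR and ChemmineOB")
  }
  sdf <- if (!is.null(ligands$sdf)) {
    ligands$sdf
  } else {
    smi <- ligands$smiles
    names(smi) <- ligands$ids
    ChemmineR::smiles2sdf(smi)
  }
  fpset <- ChemmineR::fingerprintOB(sdf, "FP2")
  m <- ChemmineR::as.matrix(fpset)
  storage.mode(m) <- "integer"
  if (ncol(m) != n_bits) {
    stop(sprintf("engine produced %d bits, expected %d", ncol(m), n_bits))
  }
  rownames(m) <- ligands$ids
  attr(m, "engine") <- "OpenBabel FP2 (ChemmineOB)"
  attr(m, "engine_version") <- as.character(utils::packageVersion("ChemmineOB"))
  m
}

#' Compute and standardize the continuous descriptor channel
#'
#' Physicochemical descriptors (OpenBabel property set via ChemmineR) or a
#' supplied raw descriptor matrix, standardized per feature to mean 0 and
#' SD 1 over the reference collection. Constant (zero-variance) columns are
#' dropped and recorded. The returned standardization parameters must be
#' reused, via [apply_standardization()], on any query molecule so that
#' query descriptors live on the training scale.
#'
#' @param ligands A `wes_ligands` object or a numeric matrix of raw
#'   descriptors (rows = ligands).
#' @return List with `desc` (standardized matrix), `params` (data frame
#'   `feature, mu, sigma` for retained columns) and `dropped` (names of
#'   constant columns).
#' @export
compute_continuous_features <- function(ligands) {
  if (!is.matrix(ligands)) {
    stopifnot(inherits(ligands, "wes_ligands"))
    if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
      stop("descriptor computation requires ChemmineR and ChemmineOB")
    }
    sdf <- if (!is.null(ligands$sdf)) {
      ligands$sdf
    } else {
      smi <- ligands$smiles
      names(smi) <- ligands$ids
      ChemmineR::smiles2sdf(smi)
    }
    pr <- ChemmineR::propOB(sdf)
    keep <- vapply(pr, is.numeric, logical(1))
    m <- as.matrix(pr[, keep, drop = FALSE])
    rownames(m) <- ligands$ids
  } else {
    m <- ligands
  }
  if (is.null(colnames(m))) colnames(m) <- sprintf("d%04d", seq_len(ncol(m)))
  mu <- colMeans(m)
  sigma <- apply(m, 2L, stats::sd)
  constant <- !is.finite(sigma) | sigma == 0
  if (all(constant)) stop("all descriptor columns are constant")
  m <- m[, !constant, drop = FALSE]
  params <- data.frame(
    feature = colnames(m), mu = mu[!constant], sigma = sigma[!constant],
    stringsAsFactors = FALSE, row.names = NULL
  )
  std <- sweep(sweep(m, 2L, params$mu), 2L, params$sigma, `/`)
  list(desc = std, params = params, dropped = names(sigma)[constant])
}

#' Read / write a feature matrix as delimited text
#'
#' Tab-separated with a `ligand_id` index column followed by one column per
#' feature; the interchange format used by the command-line interface for
#' both channels (and by the synthetic path, so synthetic and real data
#' flow through identical files).
#'
#' @param path File path.
#' @return `read_feature_matrix`: numeric matrix with ligand ids as row
#'   names.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("feature file not found: %s", path))
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1L] != "ligand_id") {
    stop("first column must be 'ligand_id'")
  }
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x$ligand_id
  storage.mode(m) <- if (all(m %in% c(0, 1))) "integer" else "double"
  m
}

#' @rdname read_feature_matrix
#' @param m Matrix with ligand ids as row names.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(!is.null(rownames(m)))
  df <- data.frame(
    ligand_id = rownames(m), m,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Standardize query descriptors with stored training parameters
#'
#' @param m Raw descriptor matrix (query molecules x features; must contain
#'   every retained training feature).
#' @param params Standardization parameters from
#'   [compute_continuous_features()].
#' @return Standardized matrix with columns ordered as in training.
#' @export
apply_standardization <- function(m, params) {
  miss <- setdiff(params$feature, colnames(m))
  if (length(miss)) {
    stop(sprintf(
      "query matrix lacks descriptor(s): %s",
      paste(utils::head(miss, 5L), collapse = ", ")
    ))
  }
  m <- m[, params$feature, drop = FALSE]
  sweep(sweep(m, 2L, params$mu), 2L, params$sigma, `/`)
}
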