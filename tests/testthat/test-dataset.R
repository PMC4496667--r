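test_that("the filter fixture is pruned to the documented survivor set", {
  fx <- make_filter_fixture()
  res <- filter_positive_set(fx$interactions, fp = fx$fp)
  got <- res$records[order(res$records$protein_id, res$records$ligand_id), ]
  rownames(got) <- NULL
  expect_equal(
    got[, c("protein_id", "ligand_id")],
    fx$expected_survivors[order(
      fx$expected_survivors$protein_id,
      fx$expected_survivors$ligand_id
    ), ]
  )
  # every rule fires at least once on the fixture
  rep <- res$report
  for (step in c("dedupe", "affinity", "overlap", "tanimoto", "min_size")) {
    expect_gt(rep[[step]]$before - rep[[step]]$after, 0)
  }
  # counts are monotone non-increasing through the cascade
  counts <- c(
    rep$dedupe$before, rep$dedupe$after, rep$affinity$after,
    rep$overlap$after, rep$tanimoto$after, rep$min_size$after
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("filtering is idempotent and stable on already-clean input", {
  fx <- make_filter_fixture()
  first <- filter_positive_set(fx$interactions, fp = fx$fp)
  again <- filter_positive_set(first$records, fp = fx$fp)
  expect_equal(
    again$records[, c("protein_id", "ligand_id")],
    first$records[, c("protein_id", "ligand_id")]
  )
  for (step in c("dedupe", "affinity", "overlap", "tanimoto", "min_size")) {
    expect_equal(again$report[[step]]$before, again$report[[step]]$after)
  }
})

test_that("mixed Ki/IC50 measurements are averaged in micromolar", {
  # Ki 5 + IC50 20 -> mean 12.5 > 10 -> removed; Ki 5 + IC50 9 -> kept
  tab <- data.frame(
    protein_id = rep("P1", 12),
    ligand_id = c("LA", "LA", "LB", "LB", paste0("L", 1:8)),
    affinity_type = c("Ki", "IC50", "Ki", "IC50", rep("Ki", 8)),
    affinity_uM = c(5, 20, 5, 9, rep(1, 8)),
    stringsAsFactors = FALSE
  )
  fp <- diag(1L, 10)
  rownames(fp) <- c("LA", "LB", paste0("L", 1:8))
  res <- filter_positive_set(tab, fp = fp)
  expect_false("LA" %in% res$records$ligand_id)
  lb <- res$records[res$records$ligand_id == "LB", ]
  expect_equal(lb$affinity_uM, 7)
})

test_that("intra-set Tanimoto ceiling holds after rule four", {
  set.seed(55)
  n <- 14
  fp <- matrix(rbits(n * 24, 0.5), n, 24)
  rownames(fp) <- sprintf("L%02d", 1:n)
  fp[2, ] <- fp[1, ] # exact duplicate pair, Tc = 1
  fp[4, ] <- fp[3, ]
  fp[4, 1] <- 1 - fp[4, 1] # near duplicate
  tab <- data.frame(
    protein_id = "P1", ligand_id = rownames(fp),
    affinity_type = "Ki", affinity_uM = 1, stringsAsFactors = FALSE
  )
  res <- filter_positive_set(tab, fp = fp)
  kept <- res$records$ligand_id
  m <- fp[kept, ]
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  tc <- inter / (outer(ones, ones, `+`) - inter)
  diag(tc) <- 0
  expect_lte(max(tc), 0.75)
  expect_gte(length(kept), 5)
})

test_that("empty filtered output is fatal with per-step counts", {
  tab <- data.frame(
    protein_id = "P1", ligand_id = c("L1", "L2"),
    affinity_type = "Ki", affinity_uM = c(50, 90), stringsAsFactors = FALSE
  )
  expect_error(
    suppressWarnings(filter_positive_set(tab)),
    "no interactions survive"
  )
})

test_that("negative set matches positive count, is disjoint and seeded", {
  fx <- make_filter_fixture()
  pos <- filter_positive_set(fx$interactions, fp = fx$fp)$records
  prot <- unique(fx$interactions$protein_id)
  lig <- unique(fx$interactions$ligand_id)
  neg <- generate_negative_set(pos, prot, lig, seed = 4L)
  expect_equal(nrow(neg), nrow(pos))
  expect_true(all(neg$label == 0L))
  key <- function(d) paste(d$protein_id, d$ligand_id)
  expect_length(intersect(key(neg), key(pos)), 0)
  expect_false(any(duplicated(key(neg))))
  neg2 <- generate_negative_set(pos, prot, lig, seed = 4L)
  expect_identical(neg, neg2)
  neg3 <- generate_negative_set(pos, prot, lig, seed = 5L)
  expect_false(identical(neg, neg3))
  expect_error(
    generate_negative_set(pos, "P1", c("A1", "A2"), n = 50),
    "not enough"
  )
})

test_that("interaction tables round-trip through the TSV reader", {
  fx <- make_filter_fixture()
  path <- tempfile(fileext = ".tsv")
  utils::write.table(fx$interactions, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  back <- read_interactions(path)
  expect_equal(back$protein_id, fx$interactions$protein_id)
  expect_equal(back$affinity_uM, fx$interactions$affinity_uM)
  expect_error(read_interactions(tempfile()), "not found")
  bad <- tempfile(fileext = ".tsv")
  writeLines("a\tb", bad)
  expect_error(read_interactions(bad), "missing columns")
})
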