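# Housekeeping normalization, detectability, clustering, efficiency QC.

hk4 <- c("HK1", "HK2", "HK3", "HK4")

# Ct table from a named list gene -> vector over replicates, one condition
ct_one_cond <- function(gene_cts, tissue = "leaf", stage = "-") {
  rows <- do.call(rbind, lapply(names(gene_cts), function(g) {
    data.frame(gene_id = g, tissue = tissue, stage = stage,
               replicate = seq_along(gene_cts[[g]]), ct = gene_cts[[g]],
               stringsAsFactors = FALSE)
  }))
  rows
}

test_that("delta-Ct is the housekeeping mean minus the gene Ct", {
  dat <- ct_one_cond(list(HK1 = 20, HK2 = 20, HK3 = 20, HK4 = 20,
                          gA = 25, gB = 20, gC = 15))
  rel <- normalize_ct(ct_table(dat, hk4))
  dct <- stats::setNames(rel$summary$mean_dct, rel$summary$gene_id)
  expect_equal(unname(dct["gA"]), -5)   # Ct 25 vs HK 20
  expect_equal(unname(dct["gB"]), 0)    # equal to the HK mean
  expect_equal(unname(dct["gC"]), 5)
  # non-trivial HK mean
  dat2 <- ct_one_cond(list(HK1 = 18, HK2 = 20, HK3 = 22, HK4 = 20, gA = 19))
  rel2 <- normalize_ct(ct_table(dat2, hk4))
  expect_equal(rel2$summary$mean_dct[rel2$summary$gene_id == "gA"], 1)
})

test_that("NA Ct propagates to NA delta-Ct and is excluded from means", {
  dat <- ct_one_cond(list(HK1 = c(20, 20), HK2 = c(20, 20), HK3 = c(20, 20),
                          HK4 = c(20, 20), gA = c(25, NA)))
  rel <- normalize_ct(ct_table(dat, hk4))
  s <- rel$summary[rel$summary$gene_id == "gA", ]
  expect_equal(s$mean_dct, -5)
  expect_equal(s$n_reps, 1L)
  expect_true(is.na(s$sd_dct))  # single replicate: no SD
})

test_that("a replicate with an undetected housekeeping gene is dropped for all genes", {
  dat <- ct_one_cond(list(HK1 = c(20, NA), HK2 = c(20, 20), HK3 = c(20, 20),
                          HK4 = c(20, 20), gA = c(25, 10)))
  expect_warning(rel <- normalize_ct(ct_table(dat, hk4)), "housekeeping")
  s <- rel$summary[rel$summary$gene_id == "gA", ]
  expect_equal(s$n_reps, 1L)
  expect_equal(s$mean_dct, -5)  # the Ct-10 replicate was excluded
})

test_that("shifting a gene's Ct shifts every delta-Ct by the same amount", {
  set.seed(43)
  cfg <- sim_config(seed = 43, n_expr_genes = 10, n_planted_degs = 2,
                    n_planted_down = 1, n_undetectable = 0)
  ct <- make_ct_table(cfg)
  rel1 <- normalize_ct(ct)
  d <- 1.75
  ct2 <- ct
  ct2$data$ct[ct2$data$gene_id == "SIM001"] <-
    ct2$data$ct[ct2$data$gene_id == "SIM001"] + d
  rel2 <- normalize_ct(ct2)
  a <- rel1$summary[rel1$summary$gene_id == "SIM001", "mean_dct"]
  b <- rel2$summary[rel2$summary$gene_id == "SIM001", "mean_dct"]
  expect_equal(b, a - d)
})

test_that("replicate order does not change condition summaries", {
  cfg <- sim_config(seed = 47, n_expr_genes = 8, n_planted_degs = 2,
                    n_planted_down = 1, n_undetectable = 0)
  ct <- make_ct_table(cfg)
  rel1 <- normalize_ct(ct)
  ct2 <- ct
  ct2$data <- ct2$data[sample(nrow(ct2$data)), ]
  rel2 <- normalize_ct(ct2)
  expect_equal(rel1$summary, rel2$summary)
})

test_that("a housekeeping-level gene has delta-Ct about zero", {
  dat <- ct_one_cond(list(HK1 = 21, HK2 = 21, HK3 = 21, HK4 = 21, gHK = 21))
  rel <- normalize_ct(ct_table(dat, hk4))
  expect_equal(rel$summary$mean_dct[rel$summary$gene_id == "gHK"], 0)
})

test_that("detection cutoff converts high Ct to NA on construction", {
  dat <- ct_one_cond(list(HK1 = 20, HK2 = 20, HK3 = 20, HK4 = 20, gA = 41))
  ct <- ct_table(dat, hk4, detection_cutoff = 40)
  expect_true(is.na(ct$data$ct[ct$data$gene_id == "gA"]))
})

test_that("expression clustering merges identical profiles first, outliers last", {
  conds <- expand.grid(tissue = c("leaf", "stem", "skin"), stage = "-",
                       stringsAsFactors = FALSE)
  mk <- function(g, v) data.frame(gene_id = g, tissue = conds$tissue,
                                  stage = "-", replicate = 1L, ct = v,
                                  stringsAsFactors = FALSE)
  dat <- rbind(
    do.call(rbind, lapply(hk4, function(h) mk(h, c(20, 20, 20)))),
    mk("twinA", c(24, 26, 22)), mk("twinB", c(24, 26, 22)),
    mk("solo", c(12, 30, 19)))
  rel <- normalize_ct(ct_table(dat, hk4))
  cl <- cluster_genes(rel, min_overlap = 2)
  m <- cl$hclust$merge
  # first merge joins the two identical profiles at height 0
  expect_equal(sort(cl$hclust$labels[-m[1, ]]), c("twinA", "twinB"))
  expect_equal(cl$hclust$height[1], 0)
  # the outlier joins last
  expect_equal(m[nrow(m), 2], 1L)  # second element of last merge is cluster 1
  # direct distance computation confirms the outlier is farthest
  d <- as.matrix(dist(cl$profiles))
  expect_gt(min(d["solo", c("twinA", "twinB")]), d["twinA", "twinB"])
  # permuting gene order does not change the topology
  dat2 <- dat[rev(seq_len(nrow(dat))), ]
  cl2 <- cluster_genes(normalize_ct(ct_table(dat2, hk4)), min_overlap = 2)
  expect_equal(cl$order, cl2$order)
  expect_equal(cl$newick, cl2$newick)
})

test_that("primer efficiency window is inclusive", {
  eff <- data.frame(gene_id = c("a", "b", "c", "d"),
                    efficiency = c(1.85, 1.65, 2.0, 2.05))
  qc <- efficiency_qc(eff)
  expect_equal(qc$pass, c(TRUE, FALSE, TRUE, FALSE))
  # efficiencies carried by a simulated table are evaluated the same way
  cfg <- sim_config(seed = 51, n_expr_genes = 10, n_planted_degs = 2,
                    n_planted_down = 1, n_undetectable = 0,
                    perturb_efficiency = TRUE)
  ct <- make_ct_table(cfg)
  qc2 <- efficiency_qc(ct)
  expect_equal(qc2$pass,
               ct$efficiencies$efficiency >= 1.7 &
                 ct$efficiencies$efficiency <= 2.0)
})

test_that("Ct tables round-trip through TSV with literal NA", {
  cfg <- sim_config(seed = 53, n_expr_genes = 6, n_planted_degs = 1,
                    n_planted_down = 1, n_undetectable = 1)
  ct <- make_ct_table(cfg)
  path <- tempfile(fileext = ".tsv")
  write_ct_tsv(ct, path)
  expect_true(any(grepl("\tNA$", readLines(path))))
  ct2 <- read_ct_tsv(path, cfg$hk_genes)
  expect_equal(ct2$data$ct, ct$data$ct)
  unlink(path)
})
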