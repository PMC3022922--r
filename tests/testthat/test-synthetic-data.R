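# Synthetic-data generator: construction, determinism, planted truth.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 3, targets_per_group = 2, n_expr_genes = 40,
         n_planted_degs = 8, n_planted_down = 3, n_undetectable = 2),
    list(...))
  do.call(sim_config, args)
}

test_that("config validation enforces the documented invariants", {
  expect_error(sim_config(substitution_rate = 0.5), "substitution_rate")
  expect_error(sim_config(replicates = 0), "replicates")
  expect_error(sim_config(hk_genes = c("a", "b")), "housekeeping")
  expect_error(make_reference_panel(sim_config(refs_per_group = 0)),
               "refs_per_group")
})

test_that("reference panel has the promised structure", {
  cfg <- small_cfg()
  panel <- make_reference_panel(cfg)
  lab <- panel$labels
  expect_equal(sum(lab$family == "ERF"), 12 * cfg$refs_per_group)
  expect_equal(sum(lab$family == "AP2"), cfg$refs_per_group)
  expect_equal(sum(lab$family == "RAV"), cfg$refs_per_group)
  expect_equal(sum(lab$family == "Soloist"), 1L)
  # ERF refs carry a group; families do not
  expect_true(all(!is.na(lab$group[lab$family == "ERF"])))
  expect_true(all(is.na(lab$group[lab$family != "ERF"])))
  # AP2 refs have two AP2 domain intervals, RAV one AP2 + one B3
  ap2_ref <- lab$ref_id[lab$family == "AP2"][1]
  expect_equal(sum(panel$domains$ref_id == ap2_ref &
                     panel$domains$kind == "AP2"), 2L)
  rav_ref <- lab$ref_id[lab$family == "RAV"][1]
  expect_setequal(panel$domains$kind[panel$domains$ref_id == rav_ref],
                  c("AP2", "B3"))
  # seed alignments gap-free and rectangular
  for (aln in panel$seed_alignments) {
    expect_length(unique(nchar(aln)), 1L)
    expect_false(any(grepl("-", aln, fixed = TRUE)))
  }
  # recorded domain intervals literally match the emitted sequences
  d <- panel$domains[panel$domains$ref_id == rav_ref, ][1, ]
  dom_seq <- substr(panel$proteins[[rav_ref]], d$start + 1, d$end)
  expect_equal(nchar(dom_seq), d$end - d$start)
})

test_that("zero substitution rate makes group domains identical", {
  panel <- make_reference_panel(small_cfg(substitution_rate = 0))
  for (aln in panel$seed_alignments) expect_length(unique(aln), 1L)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  d1 <- tempfile(); d2 <- tempfile()
  simulate_to_dir(cfg, d1)
  simulate_to_dir(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("target genome plants the configured defects", {
  cfg <- small_cfg(n_fused_models = 2, n_long_intron_models = 2,
                   n_pseudogenes = 1)
  panel <- make_reference_panel(cfg)
  genome <- make_target_genome(cfg, panel)
  tg <- genome$truth$genes
  expect_equal(sum(tg$defect == "fused"), 2L)
  expect_equal(sum(tg$defect == "long_intron"), 2L)
  expect_equal(sum(tg$defect == "pseudogene"), 1L)
  # fused models record their component domains (>= 2 AP2 intervals)
  for (pid in tg$protein_id[tg$defect == "fused"]) {
    nd <- sum(genome$truth$domains$protein_id == pid &
                genome$truth$domains$kind == "AP2")
    expect_gte(nd, 2L)
  }
  # long-intron models really have an intron > 10 kb
  for (gid in tg$gene_id[tg$defect == "long_intron"])
    expect_gt(max(intron_lengths(genome$models, gid)), 10000)
  # pseudogene: protein < 100 aa and two introns > 10 kb
  ps <- tg[tg$defect == "pseudogene", ]
  expect_lt(nchar(genome$proteins[[ps$protein_id]]), 100)
  expect_gte(sum(intron_lengths(genome$models, ps$gene_id) > 10000), 2L)
  # planted truth: every recorded domain interval is on a real protein
  expect_true(all(genome$truth$domains$protein_id %in% names(genome$proteins)))
})

test_that("target identity to source matches the substitution rate", {
  cfg <- small_cfg(substitution_rate = 0.05, targets_per_group = 6)
  panel <- make_reference_panel(cfg)
  genome <- make_target_genome(cfg, panel)
  tg <- genome$truth$genes
  ok <- tg$defect %in% c("none", "long_intron") & tg$source_ref %in%
    names(panel$proteins)
  ids <- vapply(which(ok), function(i) {
    a <- strsplit(panel$proteins[[tg$source_ref[i]]], "")[[1]]
    b <- strsplit(genome$proteins[[tg$protein_id[i]]], "")[[1]]
    mean(a == b)
  }, numeric(1))
  expect_equal(mean(ids), 0.95, tolerance = 0.01)
})

test_that("Ct table plants fold changes recoverable in closed form", {
  # zero noise: delta-delta-Ct recovers the planted value exactly
  cfg <- small_cfg(rep_noise_sd = 0, n_undetectable = 0,
                   planted_log2fc = c(SIM001 = 3, SIM002 = 0, SIM003 = -2.5))
  ct <- make_ct_table(cfg)
  rel <- normalize_ct(ct)
  fc <- ddct_fold_change(rel, "skin", "veraison", "ripe")
  expect_equal(fc$log2fc[fc$gene_id == "SIM001"], 3)
  expect_equal(fc$log2fc[fc$gene_id == "SIM002"], 0)
  expect_equal(fc$log2fc[fc$gene_id == "SIM003"], -2.5)
  # all unplanted genes: exactly zero
  rest <- setdiff(fc$gene_id, c("SIM001", "SIM003"))
  expect_true(all(abs(fc$log2fc[fc$gene_id %in% rest]) < 1e-12))
})

test_that("undetectable genes are emitted all-NA and flagged downstream", {
  cfg <- small_cfg(n_undetectable = 2)
  ct <- make_ct_table(cfg)
  undet <- ct$truth$undetectable
  expect_length(undet, 2L)
  expect_true(all(is.na(ct$data$ct[ct$data$gene_id %in% undet])))
  det <- detectability(normalize_ct(ct))
  expect_setequal(det$gene_id[!det$detectable], undet)
})

test_that("planting a fold change for an unknown gene errors", {
  cfg <- small_cfg(planted_log2fc = c(NOPE = 3))
  expect_error(make_ct_table(cfg), "NOPE")
})

test_that("enriched group supplies the configured fraction of up-DEGs", {
  cfg <- sim_config(seed = 9, n_expr_genes = 120, n_planted_degs = 30,
                    enrichment_fraction = 0.5, enriched_group = "IX")
  ct <- make_ct_table(cfg)
  up <- names(ct$truth$log2fc)[ct$truth$log2fc > 0]
  grp <- ct$truth$genes$group[match(up, ct$truth$genes$gene_id)]
  expect_equal(sum(grp == "IX"), 15L)
  # group sizes: enriched group is ~25% of the universe
  expect_equal(sum(ct$truth$genes$group == "IX"), 30L)
})

test_that("config YAML round-trips through read_sim_config", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 4", "targets_per_group: 2", "substitution_rate: 0.02"),
             path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 4L)
  expect_equal(cfg$substitution_rate, 0.02)
  unlink(path)
})
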