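# Gene-model reliability rules: long introns, fused-model splitting,
# pseudogene exclusion.

# two genes: one with introns of 8,400 and 35,000 bp; one single-exon
qc_models <- function() {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    chromosome = "chr1", strand = "+",
    protein_id = c("g1.p", "g2.p", "g3.p", "g4.p"),
    protein_length = c(200L, 150L, 80L, 300L),
    stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(gene_id = "g1", start = c(1L, 9001L, 45001L),
               end = c(600L, 10000L, 45600L)),          # introns 8400, 35000
    data.frame(gene_id = "g2", start = 1L, end = 450L), # single exon
    data.frame(gene_id = "g3", start = c(1L, 12081L, 27161L),
               end = c(80L, 12160L, 27240L)),           # introns 12000, 15000
    data.frame(gene_id = "g4", start = c(1L, 12451L, 27531L),
               end = c(450L, 12900L, 27980L)))          # same long introns
  gene_models(genes, exons)
}

test_that("long introns are flagged with a strict > threshold", {
  li <- flag_long_introns(qc_models())
  expect_true(li$long_intron[li$gene_id == "g1"])
  expect_equal(li$max_intron_bp[li$gene_id == "g1"], 35000L)
  expect_equal(li$n_long_introns[li$gene_id == "g1"], 1L)  # 8400 is not > 10 kb
  # single-exon model: no introns, never flagged
  expect_false(li$long_intron[li$gene_id == "g2"])
  expect_equal(li$max_intron_bp[li$gene_id == "g2"], 0L)
  # intron of exactly 10,000 bp is not flagged
  m <- gene_models(
    data.frame(gene_id = "b", chromosome = "chr1", strand = "+",
               protein_id = "b.p", protein_length = 100L),
    data.frame(gene_id = "b", start = c(1L, 10101L), end = c(100L, 10200L)))
  expect_equal(intron_lengths(m, "b"), 10000L)
  expect_false(flag_long_introns(m)$long_intron)
})

test_that("exon validation catches overlapping exons", {
  expect_error(gene_models(
    data.frame(gene_id = "x", chromosome = "c", strand = "+",
               protein_id = "x.p", protein_length = 10L),
    data.frame(gene_id = "x", start = c(1L, 50L), end = c(60L, 100L))),
    "overlapping")
})

test_that("pseudogene rule needs both short protein and two long introns", {
  ps <- flag_pseudogenes(qc_models())
  expect_true(ps$pseudogene[ps$gene_id == "g3"])   # 80 aa + 12 kb & 15 kb
  expect_false(ps$pseudogene[ps$gene_id == "g4"])  # 300 aa: length fails
  expect_false(ps$pseudogene[ps$gene_id == "g2"])  # no introns
  expect_false(ps$pseudogene[ps$gene_id == "g1"])  # only one intron > 10 kb
})

test_that("fused ERF models split at inter-hit midpoints", {
  set.seed(8)
  dom <- rand_protein(20)
  # three domain copies at known offsets
  prot <- paste0(rand_protein(10), dom, rand_protein(30), dom,
                 rand_protein(30), dom, rand_protein(10))
  starts <- c(10L, 60L, 110L)
  hits <- data.frame(protein_id = "f", kind = "AP2", start = starts,
                     end = starts + 20L, score = 1, relative_score = 1)
  sp <- split_fused_model(prot, hits, "ERF", gene_id = "f")
  expect_equal(nrow(sp), 3L)
  expect_equal(sp$product_id, c("f_a", "f_b", "f_c"))
  # products tile the protein
  expect_equal(sp$seq_start[1], 0L)
  expect_equal(sp$seq_end[3], nchar(prot))
  expect_equal(sp$seq_start[-1], sp$seq_end[-3])
  # each product contains exactly its own domain, sequence-identical
  for (i in 1:3) {
    expect_equal(substr(sp$sequence[i], sp$domain_start[i] + 1,
                        sp$domain_end[i]), dom)
  }
  # two-domain case
  sp2 <- split_fused_model(prot, hits[1:2, ], "ERF", gene_id = "f")
  expect_equal(nrow(sp2), 2L)
  # legitimate AP2 tandem architecture: no split
  expect_equal(nrow(split_fused_model(prot, hits, "AP2")), 0L)
  # fewer than two hits is not a split candidate
  expect_error(split_fused_model(prot, hits[1, ], "ERF"), "candidate")
})

test_that("QC on synthetic data flags all planted defects and no others", {
  cfg <- sim_config(seed = 13, substitution_rate = 0, targets_per_group = 2,
                    n_fused_models = 2, n_long_intron_models = 2,
                    n_pseudogenes = 1)
  panel <- make_reference_panel(cfg)
  genome <- make_target_genome(cfg, panel)
  profiles <- lapply(panel$profile_seeds, function(s)
    build_profile(s$sequences, kind = s$kind))
  hits <- scan_proteome(genome$proteins, profiles)
  qc <- qc_gene_models(genome$models, genome$proteins, hits, panel)
  truth <- genome$truth$genes
  r <- qc$report
  expect_setequal(r$gene_id[r$multi_domain],
                  truth$gene_id[truth$defect == "fused"])
  expect_setequal(r$gene_id[r$long_intron],
                  truth$gene_id[truth$defect %in% c("long_intron", "pseudogene")])
  expect_setequal(qc$excluded, truth$gene_id[truth$defect == "pseudogene"])
  # splitting conserves domains: products together carry all AP2 domains
  for (gid in r$gene_id[r$multi_domain]) {
    pid <- truth$protein_id[truth$gene_id == gid]
    k <- sum(hits$protein_id == pid & hits$kind == "AP2")
    prods <- strsplit(r$split_products[r$gene_id == gid], ";")[[1]]
    expect_length(prods, k)
    prod_hits <- scan_proteome(qc$proteins[prods], profiles)
    expect_equal(nrow(prod_hits), k)
    expect_true(all(table(prod_hits$protein_id) == 1L))
  }
  # idempotence: QC over the already-split proteome changes nothing more
  hits2 <- scan_proteome(qc$proteins, profiles)
  still_fused <- names(qc$proteins)[vapply(names(qc$proteins), function(p)
    sum(hits2$protein_id == p & hits2$kind == "AP2") >= 2 &&
      sum(hits2$protein_id == p & hits2$kind == "B3") == 0, logical(1))]
  # the only remaining multi-AP2 proteins are legitimate AP2-family ones
  fams <- vapply(still_fused, function(p) {
    nr <- nearest_reference(qc$proteins[[p]], panel)
    panel$labels$family[panel$labels$ref_id == nr$ref_id]
  }, character(1))
  expect_true(all(fams == "AP2"))
})
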