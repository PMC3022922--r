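# Delta-delta-Ct fold changes, DEG calling, Fisher enrichment, set algebra,
# profile correlation.

test_that("fold changes recover planted shifts and are antisymmetric", {
  cfg <- sim_config(seed = 57, rep_noise_sd = 0, n_expr_genes = 12,
                    n_undetectable = 0,
                    planted_log2fc = c(SIM001 = 3, SIM002 = 0))
  rel <- normalize_ct(make_ct_table(cfg))
  fc <- ddct_fold_change(rel, "skin", "veraison", "ripe")
  expect_equal(fc$log2fc[fc$gene_id == "SIM001"], 3)   # 8-fold
  expect_equal(fc$log2fc[fc$gene_id == "SIM002"], 0)
  rev_fc <- ddct_fold_change(rel, "skin", "ripe", "veraison")
  expect_equal(rev_fc$log2fc, -fc$log2fc)
  # missing stage errors
  expect_error(ddct_fold_change(rel, "skin", "veraison", "overripe"),
               "absent")
})

test_that("fold-change SD is the SD of replicate-wise differences", {
  hk <- c("HK1", "HK2", "HK3", "HK4")
  mk <- function(g, stage, cts) data.frame(
    gene_id = g, tissue = "skin", stage = stage,
    replicate = seq_along(cts), ct = cts, stringsAsFactors = FALSE)
  dat <- rbind(
    do.call(rbind, lapply(hk, function(h)
      rbind(mk(h, "veraison", c(20, 20, 20)), mk(h, "ripe", c(20, 20, 20))))),
    mk("gA", "veraison", c(25, 24, 26)), mk("gA", "ripe", c(22, 20, 21)))
  rel <- normalize_ct(ct_table(dat, hk))
  fc <- ddct_fold_change(rel, "skin", "veraison", "ripe")
  # ddct per replicate: (25-22, 24-20, 26-21) = (3, 4, 5)
  expect_equal(fc$log2fc[fc$gene_id == "gA"], 4)
  expect_equal(fc$sd[fc$gene_id == "gA"], stats::sd(c(3, 4, 5)))
  expect_equal(fc$n_pairs[fc$gene_id == "gA"], 3L)
})

test_that("noisy replicates recover planted fold changes within 3 standard errors", {
  cfg <- sim_config(seed = 61, rep_noise_sd = 0.3, n_expr_genes = 30,
                    n_undetectable = 0, n_planted_degs = 6, n_planted_down = 2)
  ct <- make_ct_table(cfg)
  rel <- normalize_ct(ct)
  fc <- ddct_fold_change(rel, "skin", "veraison", "ripe")
  planted <- ct$truth$log2fc
  # SE of the delta-delta-Ct estimate: two stage means of 3 replicates,
  # each delta-Ct has variance (1 + 1/4) * sigma^2 (gene well + HK mean of 4)
  se <- sqrt(2 * 1.25 * 0.3^2 / cfg$replicates)
  est <- fc$log2fc[match(names(planted), fc$gene_id)]
  expect_true(all(abs(est - planted) <= 3 * se))
})

test_that("DEG calling partitions at the 4-fold threshold", {
  fcs <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    log2fc = c(2.03, -2.09, 1.99, -1.99, 0),
                    sd = c(0.39, NA, 0.1, NA, 0.2),
                    stringsAsFactors = FALSE)
  degs <- call_degs(fcs, threshold_log2 = 2)
  dir <- stats::setNames(degs$direction, degs$gene_id)
  expect_equal(unname(dir[c("a", "b", "c", "d", "e")]),
               c("up", "down", "unchanged", "unchanged", "unchanged"))
  # sorted by descending |log2FC|; single-replicate calls flagged
  expect_equal(degs$gene_id[1], "b")
  expect_true(degs$low_confidence[degs$gene_id == "b"])
  expect_false(degs$low_confidence[degs$gene_id == "a"])
  # raising the threshold never grows the DEG set
  for (thr in c(0, 1, 2, 3, 9)) {
    n_thr <- sum(call_degs(fcs, thr)$direction != "unchanged")
    if (thr > 0) expect_lte(n_thr, n_prev)
    n_prev <- sum(call_degs(fcs, thr)$direction != "unchanged")
  }
})

test_that("Fisher enrichment equals exhaustive enumeration for small N", {
  # worked example: N=6, K=3, n=2, k=2 -> p = C(3,2)/C(6,2) = 3/15
  group_of <- stats::setNames(c(rep("G", 3), rep("H", 3)), paste0("g", 1:6))
  res <- fisher_group_enrichment(paste0("g", 1:2), group_of)
  expect_equal(res$p_value[res$group == "G"], 3 / 15)
  expect_equal(res$p_value[res$group == "G"],
               oracle_fisher_enum(k = 2, K = 3, N = 6, n = 2))
  # random configurations, N <= 12
  set.seed(67)
  for (i in 1:6) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 1), 1)
    gof <- stats::setNames(sample(c(rep("G", K), rep("H", N - K))),
                           paste0("g", 1:N))
    degs <- sample(names(gof), n)
    k <- sum(gof[degs] == "G")
    res <- fisher_group_enrichment(degs, gof)
    expect_equal(res$p_value[res$group == "G"],
                 oracle_fisher_enum(k, K, N, n), tolerance = 1e-12)
    # and the same table through the established implementation
    tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2, 2)
    expect_equal(res$p_value[res$group == "G"],
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
  # saturated tail: everything is a DEG -> p = 1
  res_sat <- fisher_group_enrichment(names(group_of), group_of)
  expect_equal(res_sat$p_value, c(1, 1))
})

test_that("planted group enrichment is detected in most seeded simulations", {
  hits <- 0L
  n_runs <- 100L
  for (s in seq_len(n_runs)) {
    cfg <- sim_config(seed = 100 + s, n_expr_genes = 120, n_planted_degs = 30,
                      enrichment_fraction = 0.5, enriched_group = "IX",
                      n_planted_down = 0, n_undetectable = 0)
    ct <- make_ct_table(cfg)
    rel <- normalize_ct(ct)
    fc <- ddct_fold_change(rel, "skin", "veraison", "ripe")
    degs <- call_degs(fc, 2)
    gof <- stats::setNames(ct$truth$genes$group, ct$truth$genes$gene_id)
    en <- fisher_group_enrichment(degs$gene_id[degs$direction == "up"], gof)
    if (en$p_value[en$group == "IX"] <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 80L)
})

test_that("cross-tissue set algebra uses exact name matching", {
  sets <- cross_tissue_sets(list(
    skin_up = c("VvERF072", "VvERF103", "VvAP2-3", "VvERF94"),
    flesh_up = c("VvERF072", "VvERF103", "VvAP2-3", "VvERF094")))
  # VvERF94 and VvERF094 do not match under exact comparison
  expect_setequal(sets$intersections[["skin_up & flesh_up"]],
                  c("VvAP2-3", "VvERF072", "VvERF103"))
  expect_equal(sets$unique_to$skin_up, "VvERF94")
  # disjoint lists give the empty set
  s2 <- cross_tissue_sets(list(a = c("x", "y"), b = c("z")))
  expect_length(s2$intersections[["a & b"]], 0L)
  expect_error(cross_tissue_sets(list(a = "x")), ">= 2")
})

test_that("profile correlation matches direct computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 8.0, 9.9)
  expect_equal(profile_correlation(x, y, "pearson"),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_equal(profile_correlation(x, x, "pearson"), 1)
  expect_equal(profile_correlation(x, x, "spearman"), 1)
  # monotone nonlinear transform: Spearman 1, Pearson < 1
  z <- exp(x)
  expect_equal(profile_correlation(x, z, "spearman"), 1)
  expect_lt(profile_correlation(x, z, "pearson"), 1)
  # NA pairs dropped; fewer than 3 pairs errors
  expect_equal(profile_correlation(c(x, NA), c(y, 1), "pearson"),
               profile_correlation(x, y, "pearson"))
  expect_error(profile_correlation(c(1, 2, NA), c(1, NA, 2), "pearson"),
               "pairs")
})
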