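# End-to-end orchestration: the genome survey (scan -> QC -> classify ->
# summarize -> tree -> landscape) and the expression analysis (normalize ->
# detectability -> cluster -> fold changes -> DEG calls -> enrichment ->
# set algebra), plus access to the transcribed published result tables used
# as fixtures.

#' Load a bundled result-table fixture
#'
#' The package bundles transcriptions of the published differential
#' expression tables (skin and flesh veraison-to-ripe transitions) and the
#' cross-species family/group count table. Gene names are kept exactly as
#' printed, including their inconsistencies (for example `VvERF94` in the
#' skin table versus `VvERF094` in the flesh table).
#'
#' @param name One of `"table2_skin"`, `"table3_flesh"`, `"table1_counts"`.
#' @return A data frame. DEG tables: `gene`, `log2fc`, `sd`,
#'   `family_group`; count table: `family`, `group`, per-species counts.
#' @export
ap2erf_fixture <- function(name = c("table2_skin", "table3_flesh",
                                    "table1_counts")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "ap2erf")
  if (!nzchar(path)) stopf("fixture %s not found", name)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Run the genome survey pipeline
#'
#' Chains domain scanning, gene-model QC (with splitting of fused models
#' and pseudogene exclusion), family/group classification, catalogue
#' summary, an optional NJ tree of the reference panel domains, and the
#' chromosomal landscape.
#'
#' @param panel Reference panel from [make_reference_panel()] (or an
#'   equivalent list with `proteins`, `labels`, `ap2_seed`, `b3_seed`,
#'   `motifs`).
#' @param proteins Target proteome (named character vector or FASTA path).
#' @param models A [gene_models()] object or GFF3 path.
#' @param min_relative_score Domain-scan threshold (default 0.45).
#' @param min_similarity Group-assignment similarity floor (default 0.3).
#' @param max_intron Long-intron threshold in bp (default 10000).
#' @param max_gap Tandem-cluster gap in bp (default 100000).
#' @param tree Build the reference-panel NJ tree (default TRUE).
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV/Newick.
#' @return Object of class `ap2erf_survey`: `hits`, `qc`, `assignments`,
#'   `summary`, `placements`, `chromosomes`, `clusters`, `tree`,
#'   `profiles`.
#' @export
run_survey <- function(panel, proteins, models,
                       min_relative_score = 0.45, min_similarity = 0.3,
                       max_intron = 10000, max_gap = 100000,
                       tree = TRUE, out_dir = NULL) {
  if (is.character(proteins) && length(proteins) == 1L) {
    if (!file.exists(proteins)) stopf("proteome file not found: %s", proteins)
    proteins <- read_protein_fasta(proteins)
  }
  if (is.character(models) && length(models) == 1L) models <- read_gff3(models)

  profiles <- if (!is.null(panel$profile_seeds)) {
    # representative-query scanning: one profile per group/family seed
    lapply(panel$profile_seeds, function(s)
      build_profile(s$sequences, kind = s$kind))
  } else {
    list(AP2 = build_profile(panel$ap2_seed, kind = "AP2"),
         B3 = build_profile(panel$b3_seed, kind = "B3"))
  }
  hits <- scan_proteome(proteins, profiles, min_relative_score)
  qc <- qc_gene_models(models, proteins, hits, panel,
                       max_intron = max_intron)
  # rescan split products so every catalogue entry has its own hits
  new_ids <- setdiff(names(qc$proteins), names(proteins))
  hits2 <- hits[hits$protein_id %in% names(qc$proteins), , drop = FALSE]
  if (length(new_ids)) {
    hits2 <- rbind(hits2, scan_proteome(qc$proteins[new_ids], profiles,
                                        min_relative_score))
    hits2 <- hits2[order(hits2$protein_id, hits2$start), , drop = FALSE]
  }
  excluded_pids <- models$genes$protein_id[models$genes$gene_id %in% qc$excluded]
  catalogue <- qc$proteins[!(names(qc$proteins) %in% excluded_pids)]
  assignments <- classify_proteome(catalogue, hits2, panel, min_similarity)
  summ <- catalogue_summary(assignments)
  placements <- gene_placements(assignments, models)
  chrom <- chromosome_counts(placements)
  clusters <- find_tandem_clusters(placements, max_gap = max_gap)
  nj <- NULL
  if (isTRUE(tree)) {
    nj <- neighbor_joining(pairwise_distances(
      vapply(panel$labels$ref_id, function(id) panel$proteins[[id]],
             character(1))))
  }
  res <- structure(list(hits = hits2, qc = qc, assignments = assignments,
                        summary = summ, placements = placements,
                        chromosomes = chrom, clusters = clusters,
                        tree = nj, profiles = profiles),
                   class = "ap2erf_survey")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(hits2, file.path(out_dir, "domain_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(qc$report, file.path(out_dir, "qc_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summ, file.path(out_dir, "catalogue_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clusters, file.path(out_dir, "tandem_clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(nj))
      ape::write.tree(nj$tree, file.path(out_dir, "panel_nj.nwk"))
  }
  res
}

#' @export
print.ap2erf_survey <- function(x, ...) {
  a <- x$assignments[x$assignments$family != "unclassified", , drop = FALSE]
  cat(sprintf("AP2/ERF survey: %d catalogued genes (ERF %d, AP2 %d, RAV %d, Soloist %d); %d tandem cluster(s)\n",
              nrow(a), sum(a$family == "ERF"), sum(a$family == "AP2"),
              sum(a$family == "RAV"), sum(a$family == "Soloist"),
              nrow(x$clusters)))
  invisible(x)
}

#' Run the expression analysis pipeline
#'
#' Normalizes a Ct table, flags detectability, computes veraison-to-ripe
#' fold changes per berry tissue, calls DEGs, tests per-group
#' over-representation, and intersects DEG sets across tissues.
#'
#' @param ct A [ct_table()] (or TSV path plus `hk_genes`).
#' @param group_of Named character vector of group labels per gene
#'   (catalogue background for enrichment); taken from `ct$truth` when
#'   absent and available.
#' @param hk_genes Housekeeping ids, only needed when `ct` is a path.
#' @param tissues Tissues with a veraison/ripe pair (default skin, flesh).
#' @param stage_a,stage_b Transition stages.
#' @param threshold_log2 DEG threshold (default 2 = 4-fold).
#' @param alpha Enrichment significance level.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return Object of class `ap2erf_expression`: `rel`, `detect`,
#'   `fold_changes` (per tissue), `degs` (per tissue), `enrichment` (per
#'   tissue and direction), `sets`, `clustering`.
#' @export
run_expression <- function(ct, group_of = NULL, hk_genes = NULL,
                           tissues = c("skin", "flesh"),
                           stage_a = "veraison", stage_b = "ripe",
                           threshold_log2 = 2, alpha = 0.05,
                           out_dir = NULL) {
  if (is.character(ct) && length(ct) == 1L) {
    if (is.null(hk_genes)) stopf("hk_genes required when reading a Ct TSV")
    ct <- read_ct_tsv(ct, hk_genes)
  }
  if (is.null(group_of) && !is.null(ct$truth))
    group_of <- stats::setNames(ct$truth$genes$group, ct$truth$genes$gene_id)
  rel <- normalize_ct(ct)
  detect <- detectability(rel)
  fold_changes <- list(); degs <- list(); enrich <- list(); deg_lists <- list()
  for (ts in tissues) {
    fc <- ddct_fold_change(rel, ts, stage_a, stage_b)
    dg <- call_degs(fc, threshold_log2)
    fold_changes[[ts]] <- fc
    degs[[ts]] <- dg
    for (dir in c("up", "down")) {
      genes <- dg$gene_id[dg$direction == dir]
      deg_lists[[paste(ts, dir, sep = "_")]] <- genes
      if (!is.null(group_of))
        enrich[[paste(ts, dir, sep = "_")]] <-
          fisher_group_enrichment(genes, group_of, alpha)
    }
  }
  sets <- cross_tissue_sets(deg_lists, group_of)
  clust <- tryCatch(cluster_genes(rel), warning = function(w)
    suppressWarnings(cluster_genes(rel)))
  res <- structure(list(rel = rel, detect = detect,
                        fold_changes = fold_changes, degs = degs,
                        enrichment = enrich, sets = sets,
                        clustering = clust),
                   class = "ap2erf_expression")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (ts in names(degs))
      utils::write.table(degs[[ts]], file.path(out_dir,
                                               paste0("degs_", ts, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(enrich))
      utils::write.table(enrich[[nm]],
                         file.path(out_dir, paste0("enrichment_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(lapply(sets$intersections, identity),
                         file.path(out_dir, "deg_sets.json"),
                         auto_unbox = FALSE, pretty = TRUE)
  }
  res
}

#' @export
print.ap2erf_expression <- function(x, ...) {
  for (ts in names(x$degs)) {
    d <- x$degs[[ts]]
    cat(sprintf("%s: %d up, %d down (|log2FC| threshold applied)\n", ts,
                sum(d$direction == "up"), sum(d$direction == "down")))
  }
  cat(sprintf("%d gene(s) undetectable\n", sum(!x$detect$detectable)))
  invisible(x)
}

#' Analyze the transcribed published DEG tables
#'
#' Re-applies the DEG call, cross-tissue set algebra and group enrichment
#' to the bundled skin/flesh fixture tables, using the bundled
#' cross-species count table as the catalogue background (ERF-IX 40 of
#' 149 genes).
#'
#' @param threshold_log2 DEG threshold (default 2).
#' @param alpha Enrichment significance level (default 0.05).
#' @return List: `skin`, `flesh` (called DEG tables), `sets`,
#'   `enrichment_skin_up` (per-group Fisher results for the skin
#'   up-regulated list), `counts` (per tissue/direction totals).
#' @export
analyze_fixture_tables <- function(threshold_log2 = 2, alpha = 0.05) {
  skin <- call_degs(ap2erf_fixture("table2_skin"), threshold_log2)
  flesh <- call_degs(ap2erf_fixture("table3_flesh"), threshold_log2)
  counts <- ap2erf_fixture("table1_counts")
  sets <- cross_tissue_sets(list(
    skin_up = skin$gene[skin$direction == "up"],
    flesh_up = flesh$gene[flesh$direction == "up"],
    skin_down = skin$gene[skin$direction == "down"],
    flesh_down = flesh$gene[flesh$direction == "down"]))
  # catalogue background from the count table: group sizes over total genes
  N <- sum(counts$vitis)
  K_ix <- counts$vitis[counts$family == "ERF" & counts$group == "IX"]
  skin_up <- skin[skin$direction == "up", , drop = FALSE]
  k <- sum(skin_up$family_group == "ERF-IX")
  n <- nrow(skin_up)
  p_ix <- stats::phyper(k - 1, K_ix, N - K_ix, n, lower.tail = FALSE)
  enrich <- data.frame(group = "IX", k = k, n = n, K = K_ix, N = N,
                       p_value = p_ix, significant = p_ix <= alpha,
                       stringsAsFactors = FALSE)
  list(skin = skin, flesh = flesh, sets = sets,
       enrichment_skin_up = enrich,
       counts = data.frame(
         tissue = c("skin", "skin", "flesh", "flesh"),
         direction = c("up", "down", "up", "down"),
         n = c(sum(skin$direction == "up"), sum(skin$direction == "down"),
               sum(flesh$direction == "up"), sum(flesh$direction == "down")),
         stringsAsFactors = FALSE))
}
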