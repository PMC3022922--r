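# Synthetic data: reference panels, target proteomes with planted gene-model
# defects, and Ct tables with planted expression structure. Everything is
# deterministic given the config seed; ground truth is returned alongside the
# emitted data so recovery can be checked by direct inspection.

# Canonical synthetic domain consensi. Modeled on the residue composition of
# plant AP2 and B3 DNA-binding domains; 58 and 50 aa respectively.
AP2_CONSENSUS <- "SGYRGVRQRPWGKFAAEIRDPAKNGARVWLGTFETAEEAALAYDRAAYSMRGSRALLN"
B3_CONSENSUS  <- "LFEKVLTPSDVGKLNRLVIPKQHAERYFPLDSSNNQNGTLLNFQDRNGKM"

ERF_GROUP_LABELS <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                      "IX", "X", "VI-L", "Xb-L")

random_residues <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Substitute each site independently with probability `rate`, always to a
# different residue, so expected identity to the source is exactly 1 - rate.
mutate_protein <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- seq_chars(seq)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) sample(setdiff(AA20, a), 1L),
                         character(1))
  }
  chars_seq(chars)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study design the package emulates: 12 ERF similarity groups (I-X,
#' VI-L, Xb-L), 58-aa AP2 and 50-aa B3 domains, four housekeeping genes,
#' five tissues with two berry ripening stages (veraison, ripe), and three
#' biological replicates per sample.
#'
#' @param seed Integer RNG seed; every generator output is a pure function
#'   of the config including this seed.
#' @param n_groups Number of ERF groups (max 12, labeled I..X, VI-L, Xb-L).
#' @param refs_per_group Reference proteins per group.
#' @param targets_per_group Target-proteome genes derived from each group
#'   (and from the AP2 and RAV families).
#' @param domain_length_ap2,domain_length_b3 Domain lengths in amino acids.
#' @param substitution_rate Per-site substitution probability in [0, 0.5)
#'   applied when deriving targets from references.
#' @param n_fused_models Number of planted fused gene models, each
#'   concatenating 2-3 single-domain ERF proteins.
#' @param n_long_intron_models Number of planted models with one intron
#'   longer than 10 kb.
#' @param n_pseudogenes Number of planted pseudogenes (protein < 100 aa with
#'   two introns > 10 kb).
#' @param hk_genes Exactly four housekeeping gene identifiers.
#' @param tissues Data frame with columns `tissue`, `stage` listing the
#'   sampled conditions.
#' @param replicates Biological replicates per condition (>= 1).
#' @param ct_base_mean Housekeeping-gene mean Ct.
#' @param rep_noise_sd Replicate noise SD in Ct units.
#' @param detection_cutoff Ct above which a well is reported undetected (NA).
#' @param n_expr_genes Size of the expression gene universe.
#' @param n_planted_degs Number of planted up-regulated genes in the
#'   `deg_tissue` veraison-to-ripe transition.
#' @param n_planted_down Number of planted down-regulated genes.
#' @param planted_log2fc Optional named numeric vector of per-gene planted
#'   log2 fold changes overriding the automatic planting.
#' @param deg_tissue Tissue carrying the planted transition (default skin).
#' @param enriched_group Group over-represented among planted up-DEGs.
#' @param enrichment_fraction Fraction of planted up-DEGs drawn from
#'   `enriched_group`.
#' @param n_undetectable Genes emitted as NA in every sample.
#' @param perturb_efficiency If TRUE, emit per-primer efficiencies drawn
#'   from U(1.6, 2.05) for efficiency QC exercises; Ct planting itself
#'   always uses the efficiency-2 convention.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_groups = 12L,
                       refs_per_group = 3L,
                       targets_per_group = 5L,
                       domain_length_ap2 = 58L,
                       domain_length_b3 = 50L,
                       substitution_rate = 0.05,
                       n_fused_models = 2L,
                       n_long_intron_models = 2L,
                       n_pseudogenes = 1L,
                       hk_genes = c("HK_EF1a", "HK_UBI", "HK_ACT", "HK_GAPDH"),
                       tissues = NULL,
                       replicates = 3L,
                       ct_base_mean = 25,
                       rep_noise_sd = 0.3,
                       detection_cutoff = 40,
                       n_expr_genes = 120L,
                       n_planted_degs = 30L,
                       n_planted_down = 8L,
                       planted_log2fc = NULL,
                       deg_tissue = "skin",
                       enriched_group = "IX",
                       enrichment_fraction = 0.5,
                       n_undetectable = 5L,
                       perturb_efficiency = FALSE) {
  if (is.null(tissues)) {
    tissues <- data.frame(
      tissue = c("leaf", "stem", "inflorescence", "skin", "skin", "flesh", "flesh"),
      stage = c("-", "-", "-", "veraison", "ripe", "veraison", "ripe"),
      stringsAsFactors = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_groups = as.integer(n_groups),
              refs_per_group = as.integer(refs_per_group),
              targets_per_group = as.integer(targets_per_group),
              domain_length_ap2 = as.integer(domain_length_ap2),
              domain_length_b3 = as.integer(domain_length_b3),
              substitution_rate = substitution_rate,
              n_fused_models = as.integer(n_fused_models),
              n_long_intron_models = as.integer(n_long_intron_models),
              n_pseudogenes = as.integer(n_pseudogenes),
              hk_genes = hk_genes, tissues = tissues,
              replicates = as.integer(replicates),
              ct_base_mean = ct_base_mean, rep_noise_sd = rep_noise_sd,
              detection_cutoff = detection_cutoff,
              n_expr_genes = as.integer(n_expr_genes),
              n_planted_degs = as.integer(n_planted_degs),
              n_planted_down = as.integer(n_planted_down),
              planted_log2fc = planted_log2fc,
              deg_tissue = deg_tissue,
              enriched_group = enriched_group,
              enrichment_fraction = enrichment_fraction,
              n_undetectable = as.integer(n_undetectable),
              perturb_efficiency = isTRUE(perturb_efficiency))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$seed, min = 0)) stopf("seed must be a non-negative integer")
  if (cfg$n_groups < 1L || cfg$n_groups > length(ERF_GROUP_LABELS))
    stopf("n_groups must be in 1..%d", length(ERF_GROUP_LABELS))
  if (cfg$substitution_rate < 0 || cfg$substitution_rate >= 0.5)
    stopf("substitution_rate must be in [0, 0.5)")
  if (cfg$replicates < 1L) stopf("replicates must be >= 1")
  if (length(cfg$hk_genes) != 4L) stopf("exactly 4 housekeeping genes required")
  if (!all(c("tissue", "stage") %in% names(cfg$tissues)))
    stopf("tissues must have columns tissue, stage")
  if (cfg$rep_noise_sd < 0) stopf("rep_noise_sd must be >= 0")
  invisible(cfg)
}

#' Read a simulation config from YAML
#'
#' @param path YAML file whose top-level keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$tissues)) args$tissues <- as.data.frame(args$tissues)
  if (!is.null(args$planted_log2fc))
    args$planted_log2fc <- unlist(args$planted_log2fc)
  do.call(sim_config, args)
}

group_motifs <- function(label, idx) {
  # 1-3 short conserved motifs per group, outside the DNA-binding domain
  n <- 1L + (idx %% 3L)
  vapply(seq_len(n), function(j) random_residues(7L), character(1))
}

#' Generate a labeled reference protein panel
#'
#' Builds, for each ERF group, a distinct AP2-domain consensus variant and a
#' set of member proteins carrying that domain plus 1-3 group-specific
#' conserved motifs in the C-terminal region; AP2-family references carry two
#' tandem AP2 domain copies separated by a linker; RAV references carry one
#' AP2 and one B3 domain; a single Soloist reference carries a divergent AP2
#' domain. Per-group seed alignments (the members' domain subsequences) are
#' gap-free by construction.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `ap2erf_panel`: `proteins` (named character),
#'   `labels` (data.frame ref_id/family/group/motifs), `seed_alignments`
#'   (per-group gap-free domain alignments), `ap2_seed`/`b3_seed` (pooled
#'   domain alignments for profile building), `domains` (true domain
#'   intervals, 0-based half-open), `motifs` (per group).
#' @export
make_reference_panel <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$refs_per_group < 1L) stopf("refs_per_group must be >= 1")
  set.seed(cfg$seed)

  ap2_base <- if (cfg$domain_length_ap2 == nchar(AP2_CONSENSUS))
    AP2_CONSENSUS else random_residues(cfg$domain_length_ap2)
  b3_base <- if (cfg$domain_length_b3 == nchar(B3_CONSENSUS))
    B3_CONSENSUS else random_residues(cfg$domain_length_b3)

  labels <- ERF_GROUP_LABELS[seq_len(cfg$n_groups)]
  proteins <- character(0)
  lab_rows <- list()
  dom_rows <- list()
  seed_alns <- list()
  motifs <- list()
  ap2_seed <- character(0)
  b3_seed <- character(0)

  emit <- function(id, seq) proteins[[id]] <<- seq

  # ERF groups: one AP2 domain + group motifs
  for (gi in seq_along(labels)) {
    g <- labels[[gi]]
    gdom <- mutate_protein(ap2_base, 0.25)
    gmot <- group_motifs(g, gi)
    motifs[[g]] <- gmot
    aln <- character(0)
    for (m in seq_len(cfg$refs_per_group)) {
      id <- sprintf("REF_%s_%02d", gsub("[^A-Za-z0-9]", "", g), m)
      dom <- mutate_protein(gdom, cfg$substitution_rate)
      nflank <- random_residues(25L)
      tail_parts <- unlist(lapply(gmot, function(mo) c(random_residues(5L), mo)))
      cpart <- paste0(paste(tail_parts, collapse = ""), random_residues(15L))
      seq <- paste0(nflank, dom, cpart)
      emit(id, seq)
      aln <- c(aln, dom)
      lab_rows[[id]] <- data.frame(ref_id = id, family = "ERF", group = g,
                                   motifs = paste(gmot, collapse = ";"),
                                   stringsAsFactors = FALSE)
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        ref_id = id, kind = "AP2", start = 25L, end = 25L + nchar(dom),
        stringsAsFactors = FALSE)
    }
    seed_alns[[g]] <- aln
    ap2_seed <- c(ap2_seed, aln)
  }

  # AP2 family: two tandem AP2 copies separated by a linker
  ap2fam_dom <- mutate_protein(ap2_base, 0.25)
  ap2fam_dom2 <- mutate_protein(ap2fam_dom, 0.10)
  ap2fam_aln <- character(0)
  for (m in seq_len(cfg$refs_per_group)) {
    id <- sprintf("REF_AP2_%02d", m)
    d1 <- mutate_protein(ap2fam_dom, cfg$substitution_rate)
    d2 <- mutate_protein(ap2fam_dom2, cfg$substitution_rate)
    nflank <- random_residues(20L)
    linker <- random_residues(25L)
    seq <- paste0(nflank, d1, linker, d2, random_residues(20L))
    emit(id, seq)
    lab_rows[[id]] <- data.frame(ref_id = id, family = "AP2", group = NA_character_,
                                 motifs = "", stringsAsFactors = FALSE)
    s1 <- 20L; s2 <- 20L + nchar(d1) + 25L
    dom_rows[[length(dom_rows) + 1L]] <- data.frame(
      ref_id = id, kind = "AP2", start = c(s1, s2),
      end = c(s1 + nchar(d1), s2 + nchar(d2)), stringsAsFactors = FALSE)
    ap2_seed <- c(ap2_seed, d1, d2)
    ap2fam_aln <- c(ap2fam_aln, d1, d2)
  }

  # RAV family: one AP2 + one B3
  rav_dom <- mutate_protein(ap2_base, 0.25)
  rav_aln <- character(0)
  for (m in seq_len(cfg$refs_per_group)) {
    id <- sprintf("REF_RAV_%02d", m)
    d1 <- mutate_protein(rav_dom, cfg$substitution_rate)
    d2 <- mutate_protein(b3_base, cfg$substitution_rate)
    nflank <- random_residues(20L)
    spacer <- random_residues(30L)
    seq <- paste0(nflank, d1, spacer, d2, random_residues(15L))
    emit(id, seq)
    lab_rows[[id]] <- data.frame(ref_id = id, family = "RAV", group = NA_character_,
                                 motifs = "", stringsAsFactors = FALSE)
    s1 <- 20L; s2 <- 20L + nchar(d1) + 30L
    dom_rows[[length(dom_rows) + 1L]] <- data.frame(
      ref_id = id, kind = c("AP2", "B3"), start = c(s1, s2),
      end = c(s1 + nchar(d1), s2 + nchar(d2)), stringsAsFactors = FALSE)
    ap2_seed <- c(ap2_seed, d1)
    rav_aln <- c(rav_aln, d1)
    b3_seed <- c(b3_seed, d2)
  }

  # Soloist: single exemplar, divergent AP2 domain
  sol_dom <- mutate_protein(ap2_base, 0.40)
  sol_id <- "REF_SOLOIST_01"
  emit(sol_id, paste0(random_residues(22L), sol_dom, random_residues(18L)))
  lab_rows[[sol_id]] <- data.frame(ref_id = sol_id, family = "Soloist",
                                   group = NA_character_, motifs = "",
                                   stringsAsFactors = FALSE)
  dom_rows[[length(dom_rows) + 1L]] <- data.frame(
    ref_id = sol_id, kind = "AP2", start = 22L, end = 22L + nchar(sol_dom),
    stringsAsFactors = FALSE)
  ap2_seed <- c(ap2_seed, sol_dom)

  # per-group/family AP2 seed alignments for representative-query scanning
  # (the single Soloist exemplar is duplicated so a profile can be built)
  profile_seeds <- c(
    lapply(seed_alns, function(a) list(kind = "AP2", sequences = a)),
    list(AP2fam = list(kind = "AP2", sequences = ap2fam_aln),
         RAV = list(kind = "AP2", sequences = rav_aln),
         Soloist = list(kind = "AP2", sequences = c(sol_dom, sol_dom)),
         B3 = list(kind = "B3", sequences = b3_seed)))

  structure(list(proteins = proteins,
                 labels = do.call(rbind, unname(lab_rows)),
                 seed_alignments = seed_alns,
                 ap2_seed = ap2_seed, b3_seed = b3_seed,
                 profile_seeds = profile_seeds,
                 domains = do.call(rbind, dom_rows),
                 motifs = motifs),
            class = "ap2erf_panel")
}

#' @export
print.ap2erf_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d proteins (%s)\n", length(x$proteins),
              paste(sprintf("%s=%d", names(table(x$labels$family)),
                            table(x$labels$family)), collapse = ", ")))
  invisible(x)
}

# Lay out a gene on a chromosome: split a CDS of 3*aa bp into exons with the
# given intron lengths. Returns exon data.frame rows (1-based inclusive).
layout_exons <- function(gene_id, cds_len, intron_lens, start_pos) {
  k <- length(intron_lens) + 1L
  base <- cds_len %/% k
  exon_lens <- rep(base, k)
  exon_lens[k] <- cds_len - base * (k - 1L)
  starts <- integer(k); ends <- integer(k)
  pos <- start_pos
  for (i in seq_len(k)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i] - 1L
    pos <- ends[i] + 1L + if (i < k) intron_lens[i] else 0L
  }
  data.frame(gene_id = gene_id, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

#' Generate a target proteome with gene models and planted defects
#'
#' Targets are per-site mutated copies of reference panel members (rate =
#' `substitution_rate`), placed on simulated chromosomes. Planted defects:
#' fused models concatenating 2-3 single-domain ERF proteins; models with
#' one intron > 10 kb; pseudogenes (protein < 100 aa with two introns
#' > 10 kb). Some same-group genes are placed within 50 kb of each other so
#' tandem-cluster detection has planted positives.
#'
#' @param cfg A [sim_config()].
#' @param panel A panel from [make_reference_panel()].
#' @return Object of class `ap2erf_genome`: `proteins` (named character,
#'   keyed by protein id), `models` (a [gene_models()] object), `truth`
#'   (list with `genes` data.frame: gene_id, protein_id, family, group,
#'   source_ref, defect, n_domains; and `domains`: true intervals).
#' @export
make_target_genome <- function(cfg, panel) {
  validate_sim_config(cfg)
  stopifnot(inherits(panel, "ap2erf_panel"))
  set.seed(cfg$seed + 1L)

  erf_labels <- panel$labels$group[panel$labels$family == "ERF"]
  erf_groups <- unique(erf_labels)
  ref_by_group <- split(panel$labels$ref_id, panel$labels$group)

  proteins <- character(0)
  gene_rows <- list(); dom_rows <- list()
  counter <- 0L
  new_gene <- function() {
    counter <<- counter + 1L
    sprintf("GENE_%04d", counter)
  }

  add_target <- function(src_id, family, group, defect = "none",
                         protein = NULL, domains = NULL) {
    gid <- new_gene()
    pid <- paste0(gid, ".p")
    if (is.null(protein)) {
      protein <- mutate_protein(panel$proteins[[src_id]], cfg$substitution_rate)
      domains <- panel$domains[panel$domains$ref_id == src_id, c("kind", "start", "end")]
    }
    proteins[[pid]] <<- protein
    gene_rows[[gid]] <<- data.frame(
      gene_id = gid, protein_id = pid, family = family,
      group = if (is.na(group)) NA_character_ else group,
      source_ref = src_id, defect = defect,
      n_domains = if (is.null(domains)) 0L else nrow(domains),
      stringsAsFactors = FALSE)
    if (!is.null(domains) && nrow(domains)) {
      dom_rows[[length(dom_rows) + 1L]] <<- cbind(
        data.frame(protein_id = pid, stringsAsFactors = FALSE), domains)
    }
    gid
  }

  for (g in erf_groups) {
    refs <- ref_by_group[[g]]
    for (t in seq_len(cfg$targets_per_group))
      add_target(refs[(t - 1L) %% length(refs) + 1L], "ERF", g)
  }
  for (fam in c("AP2", "RAV")) {
    refs <- panel$labels$ref_id[panel$labels$family == fam]
    for (t in seq_len(cfg$targets_per_group))
      add_target(refs[(t - 1L) %% length(refs) + 1L], fam, NA_character_)
  }
  add_target("REF_SOLOIST_01", "Soloist", NA_character_)

  # fused models: concatenate 2-3 fresh mutated single-domain ERF proteins
  if (cfg$n_fused_models > 0L) {
    for (f in seq_len(cfg$n_fused_models)) {
      k <- 2L + (f - 1L) %% 2L
      srcs <- sample(panel$labels$ref_id[panel$labels$family == "ERF"], k)
      parts <- lapply(srcs, function(s)
        mutate_protein(panel$proteins[[s]], cfg$substitution_rate))
      fused <- paste(unlist(parts), collapse = "")
      offs <- cumsum(c(0L, utils::head(nchar(unlist(parts)), -1L)))
      doms <- do.call(rbind, lapply(seq_along(srcs), function(i) {
        d <- panel$domains[panel$domains$ref_id == srcs[i], c("kind", "start", "end")]
        d$start <- d$start + offs[i]; d$end <- d$end + offs[i]
        d
      }))
      add_target(paste(srcs, collapse = "+"), "ERF", NA_character_,
                 defect = "fused", protein = fused, domains = doms)
    }
  }

  # pseudogenes: short protein, degenerate domain fragment
  if (cfg$n_pseudogenes > 0L) {
    for (p in seq_len(cfg$n_pseudogenes)) {
      frag <- substr(AP2_CONSENSUS, 1L, 25L)
      add_target("pseudo", "none", NA_character_, defect = "pseudogene",
                 protein = paste0(frag, random_residues(55L)), domains = NULL)
    }
  }

  genes <- do.call(rbind, unname(gene_rows))

  # mark long-intron models among ordinary ERF targets
  normal_idx <- which(genes$defect == "none" & genes$family == "ERF")
  li <- utils::head(normal_idx, cfg$n_long_intron_models)
  genes$defect[li] <- "long_intron"

  # chromosome placement: groups round-robin over 5 chromosomes; the first
  # two genes of each group are placed 20 kb apart (planted tandem cluster),
  # the rest 200 kb apart; two genes land on the unplaced scaffold chrUn
  chroms <- paste0("chr", 1:5)
  placement_key <- ifelse(is.na(genes$group), genes$family, genes$group)
  keys <- unique(placement_key)
  chrom_of_key <- stats::setNames(chroms[(seq_along(keys) - 1L) %% 5L + 1L], keys)
  cursor <- stats::setNames(rep(1L, 6), c(chroms, "chrUn"))
  exon_rows <- list()
  model_rows <- list()
  unplaced <- utils::tail(which(genes$defect == "none"), 2L)

  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    chrom <- if (i %in% unplaced) "chrUn" else chrom_of_key[[placement_key[i]]]
    aa_len <- nchar(proteins[[genes$protein_id[i]]])
    cds <- 3L * aa_len
    introns <- switch(genes$defect[i],
      long_intron = as.integer(round(stats::runif(1, 12000, 35000))),
      pseudogene = c(12000L, 15000L),
      if (i %% 4L == 0L) integer(0)
      else as.integer(round(stats::runif(sample(1:2, 1L), 500, 2000))))
    pos_in_key <- sum(placement_key[seq_len(i)] == placement_key[i])
    gap <- if (pos_in_key == 2L) 20000L else 200000L
    start_pos <- cursor[[chrom]] + gap
    ex <- layout_exons(gid, cds, introns, start_pos)
    cursor[[chrom]] <- max(ex$end)
    exon_rows[[gid]] <- ex
    model_rows[[gid]] <- data.frame(
      gene_id = gid, chromosome = chrom,
      strand = if (i %% 3L == 0L) "-" else "+",
      protein_id = genes$protein_id[i], protein_length = aa_len,
      stringsAsFactors = FALSE)
  }

  models <- gene_models(do.call(rbind, unname(model_rows)),
                        do.call(rbind, unname(exon_rows)))
  structure(list(proteins = proteins, models = models,
                 truth = list(genes = genes,
                              domains = do.call(rbind, dom_rows))),
            class = "ap2erf_genome")
}

#' @export
print.ap2erf_genome <- function(x, ...) {
  tg <- x$truth$genes
  cat(sprintf("Synthetic target genome: %d genes (%d fused, %d long-intron, %d pseudogene)\n",
              nrow(tg), sum(tg$defect == "fused"),
              sum(tg$defect == "long_intron"), sum(tg$defect == "pseudogene")))
  invisible(x)
}

#' Generate a Ct table with planted expression structure
#'
#' Housekeeping genes get Ct ~ Normal(`ct_base_mean`, `rep_noise_sd`) in every
#' sample. Each target gene has a baseline Ct plus a tissue offset; a gene
#' with planted log2 fold change f for the veraison-to-ripe transition has
#' its ripe-stage mean Ct shifted by -f (efficiency-2 convention, so the
#' downstream delta-delta-Ct recovers f). A configured fraction of planted
#' up-regulated genes is drawn from the enriched group; some genes are
#' emitted NA in every sample to emulate undetectable transcripts.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `ct_table` (see [ct_table()]) with an extra
#'   `truth` element: `genes` (gene_id, group), `log2fc` (named vector of
#'   planted fold changes, `deg_tissue` transition), `enriched_group`,
#'   `undetectable` (gene ids).
#' @export
make_ct_table <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed + 2L)

  n <- cfg$n_expr_genes
  gene_ids <- sprintf("SIM%03d", seq_len(n))
  other <- setdiff(ERF_GROUP_LABELS[seq_len(cfg$n_groups)], cfg$enriched_group)
  n_enr <- round(0.25 * n)
  groups <- c(rep(cfg$enriched_group, n_enr),
              rep_len(other, n - n_enr))
  universe <- data.frame(gene_id = gene_ids, group = groups,
                         stringsAsFactors = FALSE)

  if (is.null(cfg$planted_log2fc)) {
    n_up_enr <- round(cfg$enrichment_fraction * cfg$n_planted_degs)
    up_enr <- sample(gene_ids[groups == cfg$enriched_group], n_up_enr)
    up_oth <- sample(gene_ids[groups != cfg$enriched_group],
                     cfg$n_planted_degs - n_up_enr)
    dn <- sample(setdiff(gene_ids, c(up_enr, up_oth)), cfg$n_planted_down)
    planted <- c(stats::setNames(stats::runif(cfg$n_planted_degs, 2.5, 8),
                                 c(up_enr, up_oth)),
                 stats::setNames(-stats::runif(cfg$n_planted_down, 2.5, 6), dn))
  } else {
    planted <- cfg$planted_log2fc
    if (!all(names(planted) %in% gene_ids))
      stopf("planted gene(s) not in universe: %s",
            paste(setdiff(names(planted), gene_ids), collapse = ", "))
  }

  undet <- utils::tail(setdiff(gene_ids, names(planted)), cfg$n_undetectable)

  conds <- cfg$tissues
  tissue_levels <- unique(conds$tissue)
  tissue_off <- stats::setNames(stats::rnorm(length(tissue_levels), 0, 1),
                                tissue_levels)
  baseline <- stats::setNames(cfg$ct_base_mean + stats::rnorm(n, 0, 2), gene_ids)

  all_genes <- c(cfg$hk_genes, gene_ids)
  rows <- vector("list", nrow(conds))
  for (ci in seq_len(nrow(conds))) {
    ts <- conds$tissue[ci]; st <- conds$stage[ci]
    shift <- stats::setNames(rep(0, n), gene_ids)
    if (ts == cfg$deg_tissue && st == "ripe" && length(planted))
      shift[names(planted)] <- planted
    mu <- c(stats::setNames(rep(cfg$ct_base_mean, 4), cfg$hk_genes),
            baseline + tissue_off[[ts]] - shift)
    reps <- lapply(seq_len(cfg$replicates), function(r) {
      ct <- mu + stats::rnorm(length(mu), 0, cfg$rep_noise_sd)
      ct[names(ct) %in% undet] <- NA_real_
      ct[!is.na(ct) & ct > cfg$detection_cutoff] <- NA_real_
      data.frame(gene_id = all_genes, tissue = ts, stage = st, replicate = r,
                 ct = unname(ct), stringsAsFactors = FALSE)
    })
    rows[[ci]] <- do.call(rbind, reps)
  }
  dat <- do.call(rbind, rows)

  efficiencies <- NULL
  if (cfg$perturb_efficiency) {
    efficiencies <- data.frame(
      gene_id = all_genes,
      efficiency = round(stats::runif(length(all_genes), 1.6, 2.05), 3),
      stringsAsFactors = FALSE)
  }

  ct <- ct_table(dat, hk_genes = cfg$hk_genes,
                 detection_cutoff = cfg$detection_cutoff,
                 efficiencies = efficiencies)
  ct$truth <- list(genes = universe, log2fc = planted,
                   deg_tissue = cfg$deg_tissue,
                   enriched_group = cfg$enriched_group,
                   undetectable = undet)
  ct
}

#' Write synthetic outputs to a directory
#'
#' Emits the panel FASTA + label TSV, the target proteome FASTA + GFF3, the
#' Ct TSV, and the ground truth as JSON.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of written paths.
#' @export
simulate_to_dir <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- make_reference_panel(cfg)
  genome <- make_target_genome(cfg, panel)
  ct <- make_ct_table(cfg)
  paths <- list(
    panel_fasta = file.path(dir, "panel.faa"),
    panel_labels = file.path(dir, "panel_labels.tsv"),
    proteome = file.path(dir, "proteome.faa"),
    gff3 = file.path(dir, "models.gff3"),
    ct = file.path(dir, "ct_table.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_protein_fasta(panel$proteins, paths$panel_fasta)
  utils::write.table(panel$labels, paths$panel_labels, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_protein_fasta(genome$proteins, paths$proteome)
  write_gff3(genome$models, paths$gff3)
  write_ct_tsv(ct, paths$ct)
  truth <- list(genes = genome$truth$genes, domains = genome$truth$domains,
                expression = ct$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
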