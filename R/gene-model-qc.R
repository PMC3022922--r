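# Gene-model reliability rules: automated structural predictions of
# transcription-factor loci are error-prone, so models with implausibly long
# introns are flagged, models encoding two or more single-domain ERF proteins
# are split into one product per domain, and short models with multiple long
# introns are excluded as likely pseudogenes.

#' Flag gene models with unrealistically long introns
#'
#' @param models A [gene_models()] object.
#' @param max_intron Intron length threshold in bp; introns strictly longer
#'   are considered unreliable (default 10000).
#' @return Data frame: `gene_id`, `long_intron` (logical),
#'   `max_intron_bp`, `n_long_introns`.
#' @export
flag_long_introns <- function(models, max_intron = 10000) {
  stopifnot(inherits(models, "gene_models"))
  res <- lapply(models$genes$gene_id, function(gid) {
    il <- intron_lengths(models, gid)
    data.frame(gene_id = gid,
               long_intron = any(il > max_intron),
               max_intron_bp = if (length(il)) max(il) else 0L,
               n_long_introns = sum(il > max_intron),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Flag likely pseudogenes
#'
#' A model is flagged when its protein is shorter than `min_protein_len`
#' amino acids and it carries at least `min_long_introns` introns longer
#' than 10 kb. Flagged models are excluded from the family catalogue
#' downstream.
#'
#' @param models A [gene_models()] object.
#' @param min_protein_len Protein length floor in aa (default 100, well
#'   below any single-domain ERF protein).
#' @param min_long_introns Minimum count of > 10 kb introns (default 2).
#' @return Data frame: `gene_id`, `pseudogene` (logical).
#' @export
flag_pseudogenes <- function(models, min_protein_len = 100,
                             min_long_introns = 2) {
  stopifnot(inherits(models, "gene_models"))
  li <- flag_long_introns(models, max_intron = 10000)
  data.frame(gene_id = models$genes$gene_id,
             pseudogene = models$genes$protein_length < min_protein_len &
               li$n_long_introns[match(models$genes$gene_id, li$gene_id)] >=
                 min_long_introns,
             stringsAsFactors = FALSE)
}

#' Split a fused multi-domain gene model
#'
#' Models predicted to encode two or more AP2/ERF domains are legitimate
#' only when the protein's nearest reference belongs to the AP2 family
#' (tandem double-domain architecture); when the nearest reference is an
#' ERF-family protein the model is split into one single-domain product per
#' hit, cutting the protein at the midpoints between adjacent hits. Product
#' ids are suffixed `_a`, `_b`, ... in domain order.
#'
#' @param protein Protein sequence of the model.
#' @param hits Data frame of AP2 domain hits on this protein (as from
#'   [scan_domains()]), >= 2 rows.
#' @param nearest_ref_family Family of the protein's nearest reference
#'   (`"ERF"` or `"AP2"`).
#' @param gene_id Identifier used to derive product ids.
#' @return Data frame of products: `product_id`, `seq_start`, `seq_end`
#'   (0-based half-open protein coordinates), `sequence`, `domain_start`,
#'   `domain_end` (domain interval within the product). Zero rows when no
#'   split is performed (legitimate AP2 architecture).
#' @export
split_fused_model <- function(protein, hits, nearest_ref_family,
                              gene_id = "gene") {
  ap2 <- hits[hits$kind == "AP2", , drop = FALSE]
  if (nrow(ap2) < 2L) stopf("not a split candidate: %d AP2 hit(s)", nrow(ap2))
  if (identical(nearest_ref_family, "AP2")) {
    return(data.frame(product_id = character(0), seq_start = integer(0),
                      seq_end = integer(0), sequence = character(0),
                      domain_start = integer(0), domain_end = integer(0),
                      stringsAsFactors = FALSE))
  }
  ap2 <- ap2[order(ap2$start), , drop = FALSE]
  k <- nrow(ap2)
  mids <- floor((ap2$end[-k] + ap2$start[-1L]) / 2)
  starts <- c(0L, mids)
  ends <- c(mids, nchar(protein))
  data.frame(
    product_id = paste0(gene_id, "_", letters[seq_len(k)]),
    seq_start = starts, seq_end = ends,
    sequence = substring(protein, starts + 1L, ends),
    domain_start = ap2$start - starts,
    domain_end = ap2$end - starts,
    stringsAsFactors = FALSE)
}

#' Run all gene-model QC rules over a proteome
#'
#' Combines [flag_long_introns()], [flag_pseudogenes()] and
#' [split_fused_model()] into one report. Fused candidates are models whose
#' protein carries >= 2 AP2 hits and no B3 hit; each is split unless its
#' nearest reference is an AP2-family protein.
#'
#' @param models A [gene_models()] object.
#' @param proteins Named character vector of protein sequences (keyed by
#'   protein id).
#' @param hits Proteome-wide hit table from [scan_proteome()].
#' @param panel Reference panel ([make_reference_panel()] or an equivalent
#'   list with `proteins` and `labels`), used to find each fused candidate's
#'   nearest reference family.
#' @param max_intron,min_protein_len,min_long_introns Rule thresholds.
#' @return Object of class `ap2erf_qc`: `report` (per-gene flags and
#'   counts), `split_products` (all products with their sequences),
#'   `proteins` (the input proteome with fused models replaced by their
#'   split products), `excluded` (pseudogene ids).
#' @export
qc_gene_models <- function(models, proteins, hits, panel,
                           max_intron = 10000, min_protein_len = 100,
                           min_long_introns = 2) {
  li <- flag_long_introns(models, max_intron)
  ps <- flag_pseudogenes(models, min_protein_len, min_long_introns)
  genes <- models$genes

  n_ap2 <- vapply(genes$protein_id, function(pid)
    sum(hits$protein_id == pid & hits$kind == "AP2"), integer(1))
  n_b3 <- vapply(genes$protein_id, function(pid)
    sum(hits$protein_id == pid & hits$kind == "B3"), integer(1))

  products <- list()
  multi <- logical(nrow(genes))
  out_proteins <- proteins
  for (i in seq_len(nrow(genes))) {
    pid <- genes$protein_id[i]
    if (n_ap2[i] < 2L || n_b3[i] > 0L || ps$pseudogene[i]) next
    nr <- nearest_reference(proteins[[pid]], panel)
    fam <- panel$labels$family[panel$labels$ref_id == nr$ref_id]
    sp <- split_fused_model(proteins[[pid]],
                            hits[hits$protein_id == pid, , drop = FALSE],
                            fam, gene_id = genes$gene_id[i])
    if (nrow(sp)) {
      multi[i] <- TRUE
      products[[genes$gene_id[i]]] <- sp
      out_proteins <- out_proteins[names(out_proteins) != pid]
      add <- stats::setNames(sp$sequence, sp$product_id)
      out_proteins <- c(out_proteins, add)
    }
  }
  split_products <- if (length(products))
    do.call(rbind, unname(Map(function(gid, sp)
      cbind(data.frame(gene_id = gid, stringsAsFactors = FALSE), sp),
      names(products), products)))
  else
    data.frame(gene_id = character(0), product_id = character(0))

  report <- data.frame(
    gene_id = genes$gene_id,
    long_intron = li$long_intron,
    multi_domain = multi,
    pseudogene = ps$pseudogene,
    max_intron_bp = li$max_intron_bp,
    n_erf_domains = n_ap2,
    split_products = vapply(genes$gene_id, function(gid) {
      if (is.null(products[[gid]])) ""
      else paste(products[[gid]]$product_id, collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE)
  rownames(report) <- NULL
  structure(list(report = report, split_products = split_products,
                 proteins = out_proteins,
                 excluded = genes$gene_id[ps$pseudogene]),
            class = "ap2erf_qc")
}

#' @export
print.ap2erf_qc <- function(x, ...) {
  r <- x$report
  cat(sprintf("Gene-model QC: %d genes; %d long-intron, %d fused (split into %d products), %d pseudogene(s) excluded\n",
              nrow(r), sum(r$long_intron), sum(r$multi_domain),
              nrow(x$split_products), sum(r$pseudogene)))
  invisible(x)
}
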