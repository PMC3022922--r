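#' Gene model container
#'
#' Holds gene-level metadata and exon intervals in the GFF3 dialect
#' (1-based, inclusive). Introns are derived as the gaps between consecutive
#' exons.
#'
#' @param genes Data frame with columns `gene_id`, `chromosome`, `strand`,
#'   `protein_id`, `protein_length`.
#' @param exons Data frame with columns `gene_id`, `start`, `end`; exons of
#'   a gene must be non-overlapping.
#' @return Object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  need_g <- c("gene_id", "chromosome", "strand", "protein_id", "protein_length")
  if (!all(need_g %in% names(genes)))
    stopf("genes needs columns: %s", paste(need_g, collapse = ", "))
  if (!all(c("gene_id", "start", "end") %in% names(exons)))
    stopf("exons needs columns gene_id, start, end")
  if (!all(exons$gene_id %in% genes$gene_id))
    stopf("exons refer to unknown gene ids")
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (gid in unique(exons$gene_id)) {
    e <- exons[exons$gene_id == gid, , drop = FALSE]
    if (any(e$end < e$start)) stopf("gene %s: exon end < start", gid)
    if (nrow(e) > 1L && any(e$start[-1L] <= e$end[-nrow(e)]))
      stopf("gene %s: overlapping or unsorted exons", gid)
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons on %d sequence(s)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chromosome))))
  invisible(x)
}

#' Intron lengths of one gene
#'
#' @param models A `gene_models` object.
#' @param gene_id Gene identifier.
#' @return Integer vector of intron lengths in bp (empty for single-exon
#'   models). Intron length is the gap between consecutive exons.
#' @export
intron_lengths <- function(models, gene_id) {
  e <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(e) < 2L) return(integer(0))
  as.integer(e$start[-1L] - e$end[-nrow(e)] - 1L)
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature and its `exon` children per gene model; the gene
#' attributes carry `protein_id` and `protein_length`.
#'
#' @param models A `gene_models` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    e <- models$exons[models$exons$gene_id == g$gene_id, , drop = FALSE]
    writeLines(sprintf(
      "%s\tap2erf\tgene\t%d\t%d\t.\t%s\t.\tID=%s;protein_id=%s;protein_length=%d",
      g$chromosome, min(e$start), max(e$end), g$strand, g$gene_id,
      g$protein_id, g$protein_length), con)
    writeLines(sprintf(
      "%s\tap2erf\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
      g$chromosome, e$start, e$end, g$strand, g$gene_id), con)
  }
  invisible(path)
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]*"), attrs))
  ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, "="), attrs))) > 0,
         sub(paste0("^.*", key, "="), "", m), NA_character_)
}

#' Read gene models from GFF3
#'
#' Reads the dialect written by [write_gff3()] (gene features with
#' `protein_id`/`protein_length` attributes, exon children linked by
#' `Parent`); tolerates extra feature types, which are ignored.
#'
#' @param path GFF3 file path.
#' @return A `gene_models` object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) != 9L
  if (any(bad)) stopf("malformed GFF3: %d line(s) without 9 fields", sum(bad))
  tab <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(tab) <- c("seqid", "source", "type", "start", "end", "score",
                  "strand", "phase", "attributes")
  tab$start <- as.integer(tab$start); tab$end <- as.integer(tab$end)
  gtab <- tab[tab$type == "gene", , drop = FALSE]
  etab <- tab[tab$type == "exon", , drop = FALSE]
  genes <- data.frame(
    gene_id = gff3_attr(gtab$attributes, "ID"),
    chromosome = gtab$seqid, strand = gtab$strand,
    protein_id = gff3_attr(gtab$attributes, "protein_id"),
    protein_length = as.integer(gff3_attr(gtab$attributes, "protein_length")),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = gff3_attr(etab$attributes, "Parent"),
    start = etab$start, end = etab$end, stringsAsFactors = FALSE)
  gene_models(genes, exons)
}
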