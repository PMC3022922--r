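# RT-qPCR expression analysis. Relative expression is Ct_HK - Ct_gene, with
# Ct_HK the arithmetic mean of four housekeeping genes in the same
# sample-replicate; higher values mean more transcript. Averaging the HK Cts
# arithmetically is the log-scale equivalent of a geometric mean of the
# linear quantities.

#' Construct a Ct table
#'
#' @param data Data frame with columns `gene_id`, `tissue`, `stage`,
#'   `replicate`, `ct` (NA for undetected wells).
#' @param hk_genes Exactly four housekeeping gene identifiers; each must be
#'   present in every (tissue, stage) condition.
#' @param detection_cutoff Ct above which a well is treated as undetected
#'   (default 40); applied on construction.
#' @param efficiencies Optional data frame `gene_id`, `efficiency` with
#'   per-primer amplification efficiencies.
#' @return Object of class `ct_table`.
#' @export
ct_table <- function(data, hk_genes, detection_cutoff = 40,
                     efficiencies = NULL) {
  need <- c("gene_id", "tissue", "stage", "replicate", "ct")
  if (!all(need %in% names(data)))
    stopf("Ct data needs columns: %s", paste(need, collapse = ", "))
  if (length(hk_genes) != 4L) stopf("exactly 4 housekeeping genes required")
  miss <- setdiff(hk_genes, data$gene_id)
  if (length(miss)) stopf("housekeeping gene(s) absent: %s",
                          paste(miss, collapse = ", "))
  data$ct[!is.na(data$ct) & data$ct > detection_cutoff] <- NA_real_
  structure(list(data = data, hk_genes = hk_genes,
                 detection_cutoff = detection_cutoff,
                 efficiencies = efficiencies),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  d <- x$data
  cat(sprintf("Ct table: %d genes x %d condition(s) x up to %d replicate(s); HK: %s\n",
              length(unique(d$gene_id)),
              nrow(unique(d[, c("tissue", "stage")])),
              max(d$replicate), paste(x$hk_genes, collapse = ", ")))
  invisible(x)
}

#' Read a Ct table from TSV
#'
#' @param path TSV with columns `gene_id`, `tissue`, `stage`, `replicate`,
#'   `ct` (literal `NA` for undetected wells).
#' @inheritParams ct_table
#' @return A `ct_table`.
#' @export
read_ct_tsv <- function(path, hk_genes, detection_cutoff = 40,
                        efficiencies = NULL) {
  dat <- utils::read.delim(path, stringsAsFactors = FALSE)
  ct_table(dat, hk_genes, detection_cutoff, efficiencies)
}

#' Write a Ct table to TSV
#'
#' @param ct A `ct_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ct_tsv <- function(ct, path) {
  utils::write.table(ct$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Normalize Ct values against the housekeeping average
#'
#' Computes, per sample-replicate, the arithmetic mean Ct of the four
#' housekeeping genes, then the relative expression
#' \eqn{\Delta Ct = Ct_{HK} - Ct_{gene}} per gene and replicate, and
#' per-condition replicate means and SDs. A replicate in which any
#' housekeeping gene is undetected is excluded for all genes in that
#' condition, with a warning.
#'
#' @param ct A [ct_table()].
#' @return Object of class `rel_expression`: `per_replicate` (gene x
#'   condition x replicate `dct` plus the raw `ct`), `summary` (per gene
#'   and condition: `mean_dct`, `sd_dct`, `n_reps`), `hk_genes`,
#'   `detection_cutoff`, `dropped_replicates`.
#' @export
normalize_ct <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  d <- ct$data
  samp_key <- paste(d$tissue, d$stage, d$replicate, sep = "\r")
  hk <- d[d$gene_id %in% ct$hk_genes, , drop = FALSE]
  hk_key <- paste(hk$tissue, hk$stage, hk$replicate, sep = "\r")
  hk_n <- tapply(!is.na(hk$ct), hk_key, sum)
  hk_mean <- tapply(hk$ct, hk_key, mean)   # NA when any HK well is NA
  bad <- names(hk_mean)[is.na(hk_mean) | hk_n < length(ct$hk_genes)]
  if (length(bad)) {
    lab <- gsub("\r", "/", bad)
    warnf("excluding %d replicate(s) with undetected housekeeping gene(s): %s",
          length(bad), paste(lab, collapse = ", "))
  }
  keep <- !(samp_key %in% bad) & !(d$gene_id %in% ct$hk_genes)
  per <- d[keep, , drop = FALSE]
  per$dct <- hk_mean[paste(per$tissue, per$stage, per$replicate, sep = "\r")] -
    per$ct
  per$dct <- unname(per$dct)
  cond_key <- paste(per$gene_id, per$tissue, per$stage, sep = "\r")
  mean_dct <- tapply(per$dct, cond_key, function(x) mean(x, na.rm = TRUE))
  sd_dct <- tapply(per$dct, cond_key, function(x)
    if (sum(!is.na(x)) >= 2) stats::sd(x, na.rm = TRUE) else NA_real_)
  n_reps <- tapply(per$dct, cond_key, function(x) sum(!is.na(x)))
  parts <- do.call(rbind, strsplit(names(mean_dct), "\r", fixed = TRUE))
  summary <- data.frame(gene_id = parts[, 1], tissue = parts[, 2],
                        stage = parts[, 3],
                        mean_dct = as.numeric(mean_dct),
                        sd_dct = as.numeric(sd_dct),
                        n_reps = as.integer(n_reps),
                        stringsAsFactors = FALSE)
  summary$mean_dct[is.nan(summary$mean_dct)] <- NA_real_
  summary <- summary[order(summary$gene_id, summary$tissue, summary$stage), ,
                     drop = FALSE]
  rownames(summary) <- NULL
  structure(list(per_replicate = per, summary = summary,
                 hk_genes = ct$hk_genes,
                 detection_cutoff = ct$detection_cutoff,
                 dropped_replicates = gsub("\r", "/", bad)),
            class = "rel_expression")
}

#' @export
print.rel_expression <- function(x, ...) {
  cat(sprintf("Relative expression (Ct_HK - Ct_gene): %d genes x %d condition(s)\n",
              length(unique(x$summary$gene_id)),
              nrow(unique(x$summary[, c("tissue", "stage")]))))
  invisible(x)
}

#' Flag detectable genes
#'
#' A gene is detectable when it has at least one non-NA Ct at or below the
#' detection cutoff in at least one sample.
#'
#' @param rel A `rel_expression` from [normalize_ct()].
#' @return Data frame: `gene_id`, `detectable`.
#' @export
detectability <- function(rel) {
  stopifnot(inherits(rel, "rel_expression"))
  per <- rel$per_replicate
  det <- tapply(!is.na(per$ct) & per$ct <= rel$detection_cutoff,
                per$gene_id, any)
  data.frame(gene_id = names(det), detectable = as.logical(det),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchically cluster genes on their expression profiles
#'
#' Clusters genes on their per-condition mean relative expression vectors
#' (Euclidean distance, average linkage). Genes with fewer than
#' `min_overlap` non-NA conditions are excluded with a warning; remaining
#' NAs are handled by pairwise-complete columns rescaled to the full
#' profile length. Input is sorted by gene id first, so the dendrogram does
#' not depend on input order.
#'
#' @param rel A `rel_expression`.
#' @param genes Optional subset of gene ids (for example one family or
#'   group) to cluster.
#' @param min_overlap Minimum number of non-NA conditions per gene
#'   (default 2).
#' @return Object of class `ap2erf_expr_clust`: `hclust`, `order` (leaf
#'   gene ids in dendrogram order), `profiles` (the clustered matrix),
#'   `newick` (dendrogram as a Newick string).
#' @export
cluster_genes <- function(rel, genes = NULL, min_overlap = 2) {
  stopifnot(inherits(rel, "rel_expression"))
  s <- rel$summary
  if (!is.null(genes)) s <- s[s$gene_id %in% genes, , drop = FALSE]
  s$cond <- paste(s$tissue, s$stage, sep = "/")
  ids <- sort(unique(s$gene_id))
  conds <- sort(unique(s$cond))
  m <- matrix(NA_real_, length(ids), length(conds),
              dimnames = list(ids, conds))
  m[cbind(match(s$gene_id, ids), match(s$cond, conds))] <- s$mean_dct
  ok <- rowSums(!is.na(m)) >= min_overlap
  if (any(!ok))
    warnf("excluding %d gene(s) with < %d non-NA conditions from clustering",
          sum(!ok), min_overlap)
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 2L) stopf("need >= 2 genes with sufficient data to cluster")
  hc <- stats::hclust(stats::dist(m), method = "average")
  structure(list(hclust = hc, order = rownames(m)[hc$order], profiles = m,
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "ap2erf_expr_clust")
}

#' @export
print.ap2erf_expr_clust <- function(x, ...) {
  cat(sprintf("Expression clustering: %d genes, %d conditions (Euclidean, average linkage)\n",
              nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}

#' Primer-efficiency quality control
#'
#' @param ct A [ct_table()] carrying per-primer efficiencies, or a data
#'   frame `gene_id`, `efficiency`.
#' @param lo,hi Inclusive acceptance window (default 1.7 to 2.0).
#' @return Data frame: `gene_id`, `efficiency`, `pass`.
#' @export
efficiency_qc <- function(ct, lo = 1.7, hi = 2.0) {
  eff <- if (inherits(ct, "ct_table")) ct$efficiencies else ct
  if (is.null(eff)) stopf("no primer efficiencies available")
  data.frame(gene_id = eff$gene_id, efficiency = eff$efficiency,
             pass = eff$efficiency >= lo & eff$efficiency <= hi,
             stringsAsFactors = FALSE)
}
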