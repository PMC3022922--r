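# Differential expression between ripening stages by the delta-delta-Ct
# method (efficiency-2 convention: a delta-delta-Ct of 1 is a 2-fold
# change), DEG calling at a log2 fold-change threshold, one-sided Fisher's
# exact test for per-group over-representation among DEGs, cross-tissue set
# algebra, and expression-profile correlation.

#' Delta-delta-Ct log2 fold changes between two stages
#'
#' For each gene, log2FC = mean relative expression at `stage_b` minus mean
#' at `stage_a` within `tissue`; the SD is the SD of replicate-wise
#' delta-delta-Ct values over replicates present at both stages (NA with
#' fewer than two paired replicates).
#'
#' @param rel A `rel_expression` from [normalize_ct()].
#' @param tissue Tissue of the transition.
#' @param stage_a,stage_b Stage labels (a = baseline, e.g. veraison;
#'   b = endpoint, e.g. ripe).
#' @return Data frame: `gene_id`, `log2fc`, `sd`, `n_pairs`, `reason` (NA
#'   or why the fold change is undefined).
#' @export
ddct_fold_change <- function(rel, tissue, stage_a, stage_b) {
  stopifnot(inherits(rel, "rel_expression"))
  per <- rel$per_replicate
  pa <- per[per$tissue == tissue & per$stage == stage_a, , drop = FALSE]
  pb <- per[per$tissue == tissue & per$stage == stage_b, , drop = FALSE]
  if (!nrow(pa) || !nrow(pb))
    stopf("stage '%s' or '%s' absent for tissue '%s'",
          stage_a, stage_b, tissue)
  ids <- sort(unique(per$gene_id))
  rows <- lapply(ids, function(g) {
    a <- pa[pa$gene_id == g, , drop = FALSE]
    b <- pb[pb$gene_id == g, , drop = FALSE]
    ma <- mean(a$dct, na.rm = TRUE); mb <- mean(b$dct, na.rm = TRUE)
    if (!sum(!is.na(a$dct)) || !sum(!is.na(b$dct))) {
      return(data.frame(gene_id = g, log2fc = NA_real_, sd = NA_real_,
                        n_pairs = 0L,
                        reason = "not detected in at least one stage",
                        stringsAsFactors = FALSE))
    }
    dd <- b$dct[match(a$replicate, b$replicate)] - a$dct
    dd <- dd[!is.na(dd)]
    data.frame(gene_id = g, log2fc = mb - ma,
               sd = if (length(dd) >= 2) stats::sd(dd) else NA_real_,
               n_pairs = length(dd), reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call differentially expressed genes
#'
#' Partitions genes into up / down / unchanged at a log2 fold-change
#' threshold (default 2, i.e. 4-fold): up when log2FC >= threshold, down
#' when <= -threshold. Records are sorted by descending |log2FC|. Calls
#' backed by fewer than two replicate pairs (no SD) are flagged
#' low-confidence but kept.
#'
#' @param fcs Data frame with columns `gene_id`, `log2fc`, and optionally
#'   `sd` and annotation columns, e.g. from [ddct_fold_change()] or a
#'   transcribed result table.
#' @param threshold_log2 |log2FC| threshold (default 2).
#' @return Input rows with `direction` (`up`/`down`/`unchanged`) and
#'   `low_confidence` added, sorted by descending |log2FC|; genes with NA
#'   log2FC are dropped.
#' @export
call_degs <- function(fcs, threshold_log2 = 2) {
  stopifnot(is.numeric(threshold_log2), threshold_log2 >= 0)
  idcol <- intersect(c("gene_id", "gene"), names(fcs))
  if (!length(idcol)) stopf("fcs needs a gene_id (or gene) column")
  x <- fcs[!is.na(fcs$log2fc), , drop = FALSE]
  x$direction <- ifelse(x$log2fc >= threshold_log2, "up",
                        ifelse(x$log2fc <= -threshold_log2, "down",
                               "unchanged"))
  x$low_confidence <- if ("sd" %in% names(x)) is.na(x$sd) else NA
  x <- x[order(-abs(x$log2fc), x[[idcol[1]]]), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' One-sided Fisher's exact test for group over-representation among DEGs
#'
#' For each group, builds the 2x2 table (in-group / out-group) x (DEG /
#' non-DEG) and computes the one-sided (greater) hypergeometric tail
#' probability — the chance of drawing at least the observed number of
#' in-group genes among the DEGs. No multiple-testing correction is applied
#' to the reported p; a Benjamini-Hochberg column is emitted alongside.
#'
#' @param deg_genes Character vector of DEG gene ids (one direction of one
#'   tissue transition).
#' @param group_of Named character vector: group label per catalogue gene.
#'   Its length is the catalogue size N.
#' @param alpha Significance level (default 0.05).
#' @return Data frame per group: `group`, `k` (in-group DEGs), `n` (DEGs),
#'   `K` (group size), `N` (catalogue size), `p_value`, `p_bh`,
#'   `significant`.
#' @export
fisher_group_enrichment <- function(deg_genes, group_of, alpha = 0.05) {
  N <- length(group_of)
  deg_genes <- intersect(deg_genes, names(group_of))
  n <- length(deg_genes)
  groups <- sort(unique(group_of[!is.na(group_of)]))
  rows <- lapply(groups, function(g) {
    K <- sum(group_of == g, na.rm = TRUE)
    if (K == 0L) return(NULL)
    k <- sum(group_of[deg_genes] == g, na.rm = TRUE)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(group = g, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value <= alpha
  rownames(out) <- NULL
  out
}

#' Cross-tissue DEG set algebra
#'
#' Intersections and differences of DEG name lists across tissues and
#' directions, using exact case-sensitive gene-name matching, plus
#' per-group tallies of each input list.
#'
#' @param deg_lists Named list (>= 2) of character vectors of gene names.
#' @param group_of Optional named character vector of group labels for the
#'   tallies.
#' @return Object of class `ap2erf_deg_sets`: `sets` (the inputs),
#'   `intersections` (per list pair), `union`, `common` (genes in all
#'   lists), `unique_to` (per list), `group_tallies`.
#' @export
cross_tissue_sets <- function(deg_lists, group_of = NULL) {
  if (length(deg_lists) < 2L) stopf("need >= 2 DEG lists")
  if (is.null(names(deg_lists)))
    names(deg_lists) <- paste0("list", seq_along(deg_lists))
  nm <- names(deg_lists)
  inter <- list()
  for (i in seq_len(length(nm) - 1L)) {
    for (j in seq.int(i + 1L, length(nm))) {
      inter[[paste(nm[i], nm[j], sep = " & ")]] <-
        sort(intersect(deg_lists[[i]], deg_lists[[j]]))
    }
  }
  unique_to <- lapply(seq_along(nm), function(i)
    sort(setdiff(deg_lists[[i]], unlist(deg_lists[-i]))))
  names(unique_to) <- nm
  tallies <- NULL
  if (!is.null(group_of)) {
    tallies <- lapply(deg_lists, function(gs)
      table(group_of[intersect(gs, names(group_of))]))
  }
  structure(list(sets = deg_lists, intersections = inter,
                 union = sort(unique(unlist(deg_lists))),
                 common = sort(Reduce(intersect, deg_lists)),
                 unique_to = unique_to, group_tallies = tallies),
            class = "ap2erf_deg_sets")
}

#' @export
print.ap2erf_deg_sets <- function(x, ...) {
  cat(sprintf("DEG set algebra over %d lists (%s)\n", length(x$sets),
              paste(sprintf("%s: %d", names(x$sets), lengths(x$sets)),
                    collapse = ", ")))
  for (nm in names(x$intersections)) {
    cat(sprintf("  %s: %d gene(s)%s\n", nm, length(x$intersections[[nm]]),
                if (length(x$intersections[[nm]]) &&
                    length(x$intersections[[nm]]) <= 6)
                  paste0(" [", paste(x$intersections[[nm]], collapse = ", "), "]")
                else ""))
  }
  invisible(x)
}

#' Correlation between two expression profiles
#'
#' @param x,y Numeric vectors of matched expression values (NAs in either
#'   drop the pair); at least 3 complete pairs required.
#' @param method `"spearman"` (ties mid-ranked) or `"pearson"`.
#' @return Correlation coefficient in [-1, 1].
#' @export
profile_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stopf("need >= 3 complete pairs, got %d", sum(ok))
  stats::cor(x[ok], y[ok], method = method)
}
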