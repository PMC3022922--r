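# Chromosomal landscape: per-chromosome counts of catalogued genes and
# detection of tandem clusters — runs of same-group genes at short genomic
# distances, the signature of recent local duplication.

#' Gene placements from assignments and gene models
#'
#' @param assignments Assignment table (gene_id keyed by protein id or gene
#'   id matching the models' `protein_id`/`gene_id`).
#' @param models A [gene_models()] object.
#' @return Data frame: `gene_id`, `chromosome`, `position` (midpoint of the
#'   model span, used for distance computations), `family`, `group`.
#' @export
gene_placements <- function(assignments, models) {
  g <- models$genes
  key <- ifelse(assignments$gene_id %in% g$gene_id, assignments$gene_id,
                g$gene_id[match(assignments$gene_id, g$protein_id)])
  # split products inherit their parent model's placement
  parent <- sub("(_[a-z])$", "", assignments$gene_id)
  key[is.na(key)] <- g$gene_id[match(parent[is.na(key)], g$gene_id)]
  span <- t(vapply(key, function(gid) {
    if (is.na(gid)) return(c(NA_real_, NA_real_))
    e <- models$exons[models$exons$gene_id == gid, , drop = FALSE]
    c(min(e$start), max(e$end))
  }, numeric(2)))
  data.frame(gene_id = assignments$gene_id,
             chromosome = g$chromosome[match(key, g$gene_id)],
             position = floor((span[, 1] + span[, 2]) / 2),
             family = assignments$family,
             group = assignments$group,
             stringsAsFactors = FALSE)
}

#' Per-chromosome family/group counts
#'
#' @param placements Data frame from [gene_placements()] (columns
#'   `chromosome`, `group`, `family`).
#' @param unplaced_chrom Chromosome name(s) treated as "not assigned to any
#'   specific chromosome" (default `"chrUn"`; NA chromosomes always count
#'   as unplaced).
#' @return List: `by_chromosome` (chromosome x group count table as a data
#'   frame, plus `total` and per-group fractions), `unplaced` (count),
#'   `total` (catalogue size).
#' @export
chromosome_counts <- function(placements, unplaced_chrom = "chrUn") {
  pl <- placements
  unpl <- is.na(pl$chromosome) | pl$chromosome %in% unplaced_chrom
  placed <- pl[!unpl, , drop = FALSE]
  key <- ifelse(is.na(placed$group), placed$family, placed$group)
  tab <- table(placed$chromosome, key)
  df <- as.data.frame.matrix(tab)
  df <- cbind(data.frame(chromosome = rownames(df), stringsAsFactors = FALSE),
              df, total = rowSums(df))
  rownames(df) <- NULL
  frac <- df[, setdiff(names(df), c("chromosome", "total")), drop = FALSE] /
    ifelse(df$total > 0, df$total, 1)
  names(frac) <- paste0("frac_", names(frac))
  list(by_chromosome = cbind(df, frac), unplaced = sum(unpl),
       total = nrow(pl))
}

#' Detect tandem clusters of same-group genes
#'
#' Within each chromosome (and each group, when `same_group` is TRUE),
#' genes are sorted by position and chained while the gap between adjacent
#' members is at most `max_gap`; maximal chains with at least `min_size`
#' members are reported, so no cluster can be extended by an adjacent
#' qualifying gene.
#'
#' @param placements Data frame from [gene_placements()].
#' @param max_gap Maximum adjacent distance in bp (default 100000).
#' @param min_size Minimum cluster size (default 2).
#' @param same_group Restrict clusters to one group (default TRUE).
#' @return Data frame: `chromosome`, `group`, `n_members`, `members`
#'   (";"-joined, ordered by position), `span_bp`, `max_adjacent_gap_bp`.
#' @export
find_tandem_clusters <- function(placements, max_gap = 100000, min_size = 2,
                                 same_group = TRUE) {
  pl <- placements[!is.na(placements$chromosome) & !is.na(placements$position), ,
                   drop = FALSE]
  if (same_group) pl <- pl[!is.na(pl$group), , drop = FALSE]
  keyed <- if (same_group) split(pl, list(pl$chromosome, pl$group), drop = TRUE)
           else split(pl, pl$chromosome)
  out <- list()
  for (blk in keyed) {
    blk <- blk[order(blk$position), , drop = FALSE]
    if (nrow(blk) < min_size) next
    gaps <- diff(blk$position)
    run_id <- cumsum(c(0L, gaps > max_gap))
    for (rid in unique(run_id)) {
      run <- blk[run_id == rid, , drop = FALSE]
      if (nrow(run) < min_size) next
      out[[length(out) + 1L]] <- data.frame(
        chromosome = run$chromosome[1],
        group = if (same_group) run$group[1] else NA_character_,
        n_members = nrow(run),
        members = paste(run$gene_id, collapse = ";"),
        span_bp = max(run$position) - min(run$position),
        max_adjacent_gap_bp = max(diff(run$position)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), group = character(0),
                      n_members = integer(0), members = character(0),
                      span_bp = numeric(0), max_adjacent_gap_bp = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$group, -res$n_members), , drop = FALSE]
}

#' Annotate genes with paralogous-segment labels
#'
#' Maps each gene to the label of the segment containing its position.
#' Segments use the BED convention: 0-based half-open `[start, end)`
#' intervals, so a gene exactly at `end` falls outside.
#'
#' @param placements Data frame from [gene_placements()].
#' @param segments Data frame with columns `chromosome`, `start`, `end`,
#'   `label` (BED-style intervals), or a path to a 4-column BED file.
#' @return `placements` with an added `segment` column (NA outside all
#'   segments).
#' @export
segment_annotation <- function(placements, segments) {
  if (is.character(segments) && length(segments) == 1L) {
    segments <- utils::read.delim(segments, header = FALSE,
                                  stringsAsFactors = FALSE)[, 1:4]
    names(segments) <- c("chromosome", "start", "end", "label")
  }
  if (!all(c("chromosome", "start", "end", "label") %in% names(segments)))
    stopf("segments need columns chromosome, start, end, label")
  if (any(segments$end <= segments$start))
    stopf("malformed segment interval(s): end <= start")
  seg_of <- function(chrom, pos) {
    if (is.na(chrom) || is.na(pos)) return(NA_character_)
    hit <- which(segments$chromosome == chrom &
                   segments$start <= pos & pos < segments$end)
    if (!length(hit)) NA_character_ else segments$label[hit[1L]]
  }
  placements$segment <- mapply(seg_of, placements$chromosome,
                               placements$position, USE.NAMES = FALSE)
  placements
}
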