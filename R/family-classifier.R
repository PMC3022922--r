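# Family and group classification: family from domain architecture (one AP2
# domain -> ERF; two tandem AP2 -> AP2; AP2 + B3 -> RAV), group from
# whole-protein similarity to the nearest labeled reference, corroborated by
# conserved motifs outside the DNA-binding domain, with a nearest-exemplar
# rule for the divergent single-copy Soloist gene.

#' Classify a gene's family from its domain architecture
#'
#' @param hits Data frame of domain hits for one protein (columns `kind`
#'   at minimum).
#' @return One of `"ERF"`, `"AP2"`, `"RAV"`, `"unclassified"`. A single AP2
#'   domain and no B3 gives ERF; two or more AP2 and no B3 gives AP2; at
#'   least one AP2 with at least one B3 gives RAV; no AP2 domain leaves the
#'   gene unclassified (excluded from the catalogue). Soloist resolution is
#'   similarity-based and happens in [assign_group()].
#' @export
classify_family <- function(hits) {
  n_ap2 <- sum(hits$kind == "AP2")
  n_b3 <- sum(hits$kind == "B3")
  if (n_ap2 == 0L) return("unclassified")
  if (n_b3 >= 1L) return("RAV")
  if (n_ap2 >= 2L) return("AP2")
  "ERF"
}

# Fraction of identical residues over aligned columns, excluding columns
# where either sequence has a gap ("pair-wise deletion" identity).
alignment_identity <- function(p, s) {
  a <- seq_chars(p); b <- seq_chars(s)
  keep <- a != "-" & b != "-"
  if (!any(keep)) return(0)
  mean(a[keep] == b[keep])
}

#' Find the nearest reference to a query protein
#'
#' Globally aligns the query against every panel reference (BLOSUM62,
#' affine gaps) and returns the reference with the highest identity over
#' aligned non-gap columns; ties are broken by lexicographic reference id.
#'
#' @param query Protein sequence (character scalar, non-empty).
#' @param panel Reference panel with `proteins` (named character) and
#'   `labels` (data.frame with `ref_id`).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return List with `ref_id` and `similarity` in [0, 1], plus
#'   `similarities`, the per-reference identity vector.
#' @export
nearest_reference <- function(query, panel, gap_opening = 10,
                              gap_extension = 0.5) {
  if (!nzchar(query)) stopf("empty query sequence")
  refs <- panel$proteins
  if (!length(refs)) stopf("empty reference panel")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(refs), Biostrings::AAString(query),
    substitutionMatrix = blosum62(), gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  # identities over aligned residue-residue columns: nmatch + nmismatch
  # excludes indel columns, i.e. pairwise-deletion identity
  nm <- Biostrings::nmatch(aln)
  cols <- nm + Biostrings::nmismatch(aln)
  sims <- ifelse(cols > 0, nm / cols, 0)
  names(sims) <- names(refs)
  ord <- order(-sims, names(sims))
  best <- ord[[1L]]
  list(ref_id = names(refs)[best], similarity = unname(sims[best]),
       similarities = sims)
}

# Count how many of the motif consensus strings occur in `sequence` outside
# the given domain intervals, allowing up to `max_mismatch` mismatches.
count_motifs <- function(sequence, motifs, domain_hits = NULL,
                         max_mismatch = 1L) {
  if (!length(motifs)) return(0L)
  masked <- sequence
  if (!is.null(domain_hits) && nrow(domain_hits)) {
    ch <- seq_chars(masked)
    for (i in seq_len(nrow(domain_hits))) {
      span <- seq.int(domain_hits$start[i] + 1L, domain_hits$end[i])
      ch[span] <- "#"
    }
    masked <- chars_seq(ch)
  }
  mch <- seq_chars(masked)
  sum(vapply(motifs, function(mo) {
    k <- nchar(mo)
    if (k > length(mch)) return(FALSE)
    mo_ch <- seq_chars(mo)
    for (s in seq_len(length(mch) - k + 1L)) {
      if (sum(mch[seq.int(s, s + k - 1L)] != mo_ch) <= max_mismatch)
        return(TRUE)
    }
    FALSE
  }, logical(1)))
}

#' Assign ERF groups and resolve the Soloist exemplar
#'
#' ERF-family genes take the group of their nearest ERF-family reference
#' when the similarity clears `min_similarity`; otherwise group NA. A
#' single-AP2 gene whose overall nearest reference is the Soloist exemplar
#' is reassigned family Soloist. Group-specific conserved motifs found
#' outside the domain are counted as corroborating evidence (never a veto).
#'
#' @param proteins Named character vector of catalogue protein sequences.
#' @param families Named character vector of families per protein id (from
#'   [classify_family()]).
#' @param hits Proteome-wide domain hit table.
#' @param panel Reference panel (with `labels` carrying `family`, `group`,
#'   `motifs`, and optionally a `motifs` list per group).
#' @param min_similarity Similarity floor for group assignment (default 0.3).
#' @return Data frame of `FamilyAssignment` rows: `gene_id`, `family`,
#'   `group`, `nearest_ref`, `similarity`, `motifs_matched`, `n_ap2`,
#'   `n_b3`.
#' @export
assign_groups <- function(proteins, families, hits, panel,
                          min_similarity = 0.3) {
  erf_mask <- panel$labels$family == "ERF"
  erf_panel <- list(proteins = panel$proteins[panel$labels$ref_id[erf_mask]],
                    labels = panel$labels[erf_mask, , drop = FALSE])
  rows <- lapply(names(proteins), function(pid) {
    fam <- families[[pid]]
    h <- hits[hits$protein_id == pid, , drop = FALSE]
    nr <- nearest_reference(proteins[[pid]], panel)
    nr_fam <- panel$labels$family[panel$labels$ref_id == nr$ref_id]
    group <- NA_character_
    motifs_matched <- 0L
    if (fam == "ERF" && identical(nr_fam, "Soloist")) {
      fam <- "Soloist"
    } else if (fam == "ERF") {
      nre <- if (identical(nr_fam, "ERF")) nr
             else nearest_reference(proteins[[pid]], erf_panel)
      if (nre$similarity >= min_similarity) {
        group <- panel$labels$group[panel$labels$ref_id == nre$ref_id]
        gmot <- panel$motifs[[group]]
        if (is.null(gmot)) {
          gmot <- strsplit(panel$labels$motifs[panel$labels$ref_id == nre$ref_id],
                           ";", fixed = TRUE)[[1]]
          gmot <- gmot[nzchar(gmot)]
        }
        motifs_matched <- count_motifs(proteins[[pid]], gmot,
                                       h[h$kind == "AP2", , drop = FALSE])
      }
    }
    data.frame(gene_id = pid, family = fam, group = group,
               nearest_ref = nr$ref_id, similarity = nr$similarity,
               motifs_matched = motifs_matched,
               n_ap2 = sum(h$kind == "AP2"), n_b3 = sum(h$kind == "B3"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a whole proteome into families and groups
#'
#' Convenience wrapper: architecture-based family per protein, then group
#' assignment and Soloist resolution. Unclassified proteins (no AP2 hit) are
#' reported but excluded from downstream catalogue summaries.
#'
#' @inheritParams assign_groups
#' @return As [assign_groups()], including unclassified rows.
#' @export
classify_proteome <- function(proteins, hits, panel, min_similarity = 0.3) {
  families <- vapply(names(proteins), function(pid)
    classify_family(hits[hits$protein_id == pid, , drop = FALSE]),
    character(1))
  cls <- names(families)[families != "unclassified"]
  assigned <- assign_groups(proteins[cls], families[cls], hits, panel,
                            min_similarity)
  uncls <- names(families)[families == "unclassified"]
  if (length(uncls)) {
    assigned <- rbind(assigned, data.frame(
      gene_id = uncls, family = "unclassified", group = NA_character_,
      nearest_ref = NA_character_, similarity = NA_real_,
      motifs_matched = 0L, n_ap2 = 0L, n_b3 = 0L, stringsAsFactors = FALSE))
  }
  assigned[order(assigned$gene_id), , drop = FALSE]
}

#' Summarize a catalogue and compare against another species
#'
#' Counts genes per family and per ERF group; when a second species' counts
#' are supplied, per-group count ratios are reported rounded to two
#' decimals.
#'
#' @param assignments Assignment table from [classify_proteome()] (or any
#'   data frame with `family`, `group`); unclassified rows are dropped.
#' @param other_counts Optional named numeric vector of the other species'
#'   counts, keyed like the summary's `key` column (ERF groups by label,
#'   families by name).
#' @return Data frame: `key` (group label or family name), `family`,
#'   `count`, and, if `other_counts` is given, `other` and `ratio`
#'   (count/other, 2 decimals; NA when the other count is 0).
#' @export
catalogue_summary <- function(assignments, other_counts = NULL) {
  a <- assignments[assignments$family != "unclassified", , drop = FALSE]
  erf <- a[a$family == "ERF", , drop = FALSE]
  keys <- list()
  for (g in ERF_GROUP_LABELS) {
    keys[[g]] <- data.frame(key = g, family = "ERF",
                            count = sum(!is.na(erf$group) & erf$group == g),
                            stringsAsFactors = FALSE)
  }
  for (fam in c("RAV", "AP2", "Soloist")) {
    keys[[fam]] <- data.frame(key = fam, family = fam,
                              count = sum(a$family == fam),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, unname(keys))
  rownames(out) <- NULL
  if (!is.null(other_counts)) {
    out$other <- as.numeric(other_counts[out$key])
    out$ratio <- ifelse(!is.na(out$other) & out$other > 0,
                        round(out$count / out$other, 2), NA_real_)
  }
  out
}

#' Count ratio between two species, 2-decimal rounding
#'
#' @param count_a,count_b Gene counts (species A over species B).
#' @return `round(count_a / count_b, 2)`.
#' @export
count_ratio <- function(count_a, count_b) round(count_a / count_b, 2)
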