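# Neighbor-joining phylogeny from pairwise-deletion p-distances, with
# column-resampling bootstrap support. NJ itself is implemented here
# (Q-criterion with Saitou-Nei distance updates and deterministic
# tie-breaking); trees are returned as ape "phylo" objects so the standard
# tree toolchain (plot, write.tree, ...) applies.

#' Pairwise-deletion p-distance matrix
#'
#' For every sequence pair, alignment columns containing a gap in either
#' sequence are dropped and the distance is the fraction of mismatching
#' retained columns. Equal-length inputs (for example a multiple alignment
#' with `-` gaps, or gap-free domain sequences) are compared column-wise
#' directly; ragged inputs are first aligned pairwise with a global
#' BLOSUM62 alignment.
#'
#' @param sequences Named character vector, >= 3 sequences.
#' @return A symmetric numeric matrix with zero diagonal, with attribute
#'   `method` = `"pairwise-deletion p-distance"`.
#' @export
pairwise_distances <- function(sequences) {
  n <- length(sequences)
  if (n < 3L) stopf("need >= 3 sequences, got %d", n)
  if (is.null(names(sequences))) names(sequences) <- paste0("t", seq_len(n))
  aligned <- length(unique(nchar(sequences))) == 1L
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  if (aligned) {
    chars <- strsplit(sequences, "", fixed = TRUE)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- chars[[i]]; b <- chars[[j]]
        keep <- a != "-" & b != "-"
        D[i, j] <- D[j, i] <- if (any(keep)) mean(a[keep] != b[keep]) else 0
      }
    }
  } else {
    for (i in seq_len(n - 1L)) {
      # one vectorized call per row: sequence i against all later sequences
      later <- seq.int(i + 1L, n)
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(sequences[later]),
        Biostrings::AAString(sequences[[i]]),
        substitutionMatrix = blosum62(), gapOpening = 10,
        gapExtension = 0.5, type = "global")
      nm <- Biostrings::nmatch(aln)
      cols <- nm + Biostrings::nmismatch(aln)
      d <- ifelse(cols > 0, Biostrings::nmismatch(aln) / cols, 0)
      D[i, later] <- D[later, i] <- d
    }
  }
  attr(D, "method") <- "pairwise-deletion p-distance"
  D
}

# smallest leaf label of each active cluster, for deterministic tie-breaking
.pair_key <- function(a, b) {
  k <- sort(c(a, b))
  paste(k[1], k[2], sep = "\r")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: at each step the pair minimizing the
#' Q-criterion \eqn{Q_{ij} = (n-2) d_{ij} - r_i - r_j} is joined, branch
#' lengths follow Saitou and Nei, and the joined pair is replaced by a node
#' at distance \eqn{d_{uk} = (d_{ik} + d_{jk} - d_{ij})/2} from every other
#' cluster. Ties in Q are broken by the lexicographically smallest pair of
#' minimum leaf labels. Negative branch-length estimates are clamped to 0
#' and counted.
#'
#' @param D Symmetric distance matrix with row/column names, n >= 3.
#' @return Object of class `ap2erf_njtree`: `tree` (an unrooted ape
#'   `phylo`), `n_clamped` (number of clamped negative branch lengths),
#'   `method`.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stopf("D must be a square matrix")
  if (max(abs(D - t(D))) > 1e-8) stopf("distance matrix is not symmetric")
  if (any(!is.finite(D))) stopf("distance matrix has non-finite entries")
  n0 <- nrow(D)
  if (n0 < 3L) stopf("need >= 3 taxa")
  method0 <- attr(D, "method") %||% "p-distance"
  labels <- rownames(D) %||% paste0("t", seq_len(n0))
  rownames(D) <- colnames(D) <- NULL

  nwk <- labels           # newick fragment per active cluster
  minleaf <- labels       # smallest leaf label per cluster, for tie-breaks
  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { n_clamped <<- n_clamped + 1L; 0 } else x
  }
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)

  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keysv <- apply(cand, 1, function(ij) .pair_key(minleaf[ij[1]], minleaf[ij[2]]))
    pick <- cand[order(keysv)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_min <- min(minleaf[i], minleaf[j])
    others <- setdiff(seq_len(n), c(i, j))
    dnew <- (D[i, others] + D[j, others] - D[i, j]) / 2
    dnew[dnew < 0] <- 0
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    nwk <- c(nwk[others], new_nwk)
    minleaf <- c(minleaf[others], new_min)
  }
  # final three clusters: closed-form star resolution
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la),
                    nwk[2], fmt(lb), nwk[3], fmt(lc))
  tree <- ape::read.tree(text = newick)
  structure(list(tree = tree, n_clamped = n_clamped, method = method0),
            class = "ap2erf_njtree")
}

#' @export
print.ap2erf_njtree <- function(x, ...) {
  cat(sprintf("Unrooted NJ tree: %d leaves, %d edges%s\n",
              length(x$tree$tip.label), nrow(x$tree$edge),
              if (x$n_clamped) sprintf(" (%d negative branch length(s) clamped to 0)",
                                       x$n_clamped) else ""))
  invisible(x)
}

# p-distances from a character matrix (taxa x columns), pairwise deletion.
matrix_pdist <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      keep <- m[i, ] != "-" & m[j, ] != "-"
      D[i, j] <- D[j, i] <- if (any(keep)) mean(m[i, keep] != m[j, keep]) else 0
    }
  }
  D
}

#' Bootstrap support for NJ tree bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the original tree the
#' percentage of replicates containing the same bipartition. All pairwise
#' distances within a replicate are computed from the same resampled column
#' index, so pairs stay consistent.
#'
#' @param alignment Named character vector of equal-length aligned sequences
#'   (gaps as `-`), or a character matrix (taxa x columns).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return Object of class `ap2erf_njboot`: `tree` (the original tree with
#'   internal `node.label` set to support values), `support` (numeric vector
#'   per internal node, percent in [0, 100]), `n_reps`.
#' @export
bootstrap_support <- function(alignment, n_reps = 1000, seed = 1) {
  if (!is.matrix(alignment)) {
    if (length(unique(nchar(alignment))) != 1L)
      stopf("alignment sequences must have equal length")
    m <- do.call(rbind, strsplit(alignment, "", fixed = TRUE))
    rownames(m) <- names(alignment) %||% paste0("t", seq_along(alignment))
  } else m <- alignment
  if (!is_count(n_reps, min = 1)) stopf("n_reps must be >= 1")
  set.seed(seed)
  main <- neighbor_joining(matrix_pdist(m))
  nc <- ncol(m)
  boots <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(nc, nc, replace = TRUE)
    boots[[b]] <- neighbor_joining(matrix_pdist(m[, idx, drop = FALSE]))$tree
  }
  counts <- ape::prop.clades(main$tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  tree <- main$tree
  tree$node.label <- format(round(support, 1), trim = TRUE)
  structure(list(tree = tree, support = support, n_reps = n_reps),
            class = "ap2erf_njboot")
}

#' @export
print.ap2erf_njboot <- function(x, ...) {
  cat(sprintf("NJ bootstrap: %d replicates; internal-edge support %s-%s%%\n",
              x$n_reps, format(min(x$support), digits = 3),
              format(max(x$support), digits = 3)))
  invisible(x)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param D Distance matrix with row names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phylip <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(c(rownames(D)[i], format(D[i, ], digits = 6)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
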