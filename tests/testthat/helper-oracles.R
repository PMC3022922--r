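# Independent oracles used to cross-check the package implementations.
# Deliberately naive: straight loops and enumeration, no shared code with
# the implementations they verify.

# All-windows domain scan: score every window by explicit residue lookup,
# return (start0, score) of every window with rel score >= threshold,
# without any overlap resolution.
oracle_all_windows <- function(protein, profile, min_rel = NULL) {
  aa <- strsplit(protein, "")[[1]]
  L <- profile$length
  out <- data.frame(start = integer(0), score = numeric(0))
  if (length(aa) < L) return(out)
  for (s in 0:(length(aa) - L)) {
    sc <- 0
    for (k in 1:L) sc <- sc + profile$weights[k, aa[s + k]]
    out <- rbind(out, data.frame(start = s, score = sc))
  }
  if (!is.null(min_rel)) out <- out[out$score / profile$max_score >= min_rel, ]
  out
}

# Brute-force neighbor joining, minimal text-book implementation kept
# independent of the package's: indices instead of label bookkeeping,
# topology returned as an ape tree via newick.
oracle_nj <- function(D) {
  labs <- rownames(D)
  nwk <- labs
  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    best <- c(NA, NA); bestq <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      q <- (n - 2) * D[i, j] - r[i] - r[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- max(0, D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    lj <- max(0, D[i, j] - D[i, j] / 2 - (r[i] - r[j]) / (2 * (n - 2)))
    newc <- sprintf("(%s:%f,%s:%f)", nwk[i], li, nwk[j], lj)
    keep <- setdiff(1:n, c(i, j))
    dn <- sapply(keep, function(k) (D[i, k] + D[j, k] - D[i, j]) / 2)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn), c(dn, 0))
    nwk <- c(nwk[keep], newc)
  }
  la <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  ape::read.tree(text = sprintf("(%s:%f,%s:%f,%s:%f);",
                                nwk[1], la, nwk[2], lb, nwk[3], lc))
}

# Exhaustive one-sided enrichment p-value: over all C(N, n) DEG subsets,
# the fraction with at least k in-group members.
oracle_fisher_enum <- function(k, K, N, n) {
  genes <- c(rep(TRUE, K), rep(FALSE, N - K))
  sets <- utils::combn(N, n)
  hits <- apply(sets, 2, function(ix) sum(genes[ix]) >= k)
  mean(hits)
}

# Additive distance matrix from tree ((A,B),(C,D)) with all branches = b.
additive_quartet <- function(b = 1) {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 2 * b
  D["C", "D"] <- D["D", "C"] <- 2 * b
  for (x in c("A", "B")) for (y in c("C", "D"))
    D[x, y] <- D[y, x] <- 3 * b
  D
}

# Distances implied by an arbitrary tree (through ape), used to make
# additive matrices for recovery tests.
tree_distances <- function(newick) {
  tr <- ape::read.tree(text = newick)
  ape::cophenetic.phylo(tr)
}

rand_protein <- function(n) {
  paste(sample(ap2erf:::AA20, n, replace = TRUE), collapse = "")
}
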