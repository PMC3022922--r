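---
title: "Methods: AP2/ERF survey and qPCR expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AP2/ERF survey and qPCR expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ap2erf)
```

## Scope

`ap2erf` implements a genome-wide survey of the AP2/ERF transcription-factor
superfamily and an RT-qPCR expression analysis around it, as one tested
pipeline: domain detection, gene-model quality control, family and group
classification, neighbor-joining phylogeny, chromosomal landscape, and
ΔCt/ΔΔCt differential expression with group-enrichment testing. Because the
original qPCR measurements and the underlying genome predictions are not
redistributable, the package ships a synthetic-data generator that emulates
the study design, plus transcriptions of the published result tables; the
methods below describe what each stage computes and which choices were open.

## Family and group model

The superfamily is defined by the AP2 DNA-binding domain (~60 aa). Family
assignment is purely architectural:

* one AP2 domain, no B3 domain → **ERF**;
* two or more AP2 domains, no B3 → **AP2** (tandem double-domain
  architecture);
* at least one AP2 plus at least one B3 → **RAV**;
* no AP2 domain → unclassified, excluded from the catalogue.

The divergent single-copy **Soloist** gene also carries one AP2 domain; it is
resolved by similarity, not architecture: a single-AP2 protein whose nearest
reference overall is the Soloist exemplar is reassigned to that family. We
deliberately do not use "single copy in the genome" as the rule — copy number
is an observation about a finished catalogue, not a decision rule applicable
to one sequence.

ERF **groups** (I–X, VI-L, Xb-L) are whole-protein similarity classes: each
ERF gene takes the group of its nearest ERF-family reference, computed by
global alignment (BLOSUM62, affine gaps, opening 10, extension 0.5) with
identity counted over aligned residue–residue columns only (columns with a
gap in either sequence are dropped — the pairwise-deletion convention used
throughout the package). Group-specific conserved motifs outside the
DNA-binding domain are counted as corroboration (`motifs_matched`, exact
match with at most one mismatch) but never veto the similarity-based call,
since motif presence degrades faster than overall similarity under
divergence. A similarity floor (default 0.3) prevents forcing arbitrarily
distant sequences into a group; below it the gene stays ERF with group `NA`.

## Domain detection

Domains are detected with position-specific scoring matrices built from
gap-free seed alignments. The weight of residue $a$ at column $c$ is

$$w_{c,a} = \log_2 \frac{(n_{c,a} + \kappa b_a) / (n + \kappa)}{b_a}$$

with counts $n_{c,a}$, $n$ sequences, background $b_a$ (uniform by default)
and pseudocount $\kappa = 1$. A window's *relative score* is its summed
weight divided by the maximum attainable score (the per-column maxima summed),
so 1 means a consensus-perfect window. Scanning slides the profile along the
protein, keeps windows at or above `min_relative_score`, and resolves
overlapping same-kind hits greedily by descending score (ties to the leftmost
start).

Two design points matter here:

* **Representative-query scanning.** The default survey builds one AP2
  profile per ERF group (from that group's seed alignment) plus profiles for
  the AP2-family, RAV and Soloist domain variants, and one B3 profile, and
  scans with all of them jointly; hits of the same kind from different
  profiles are pooled and overlap-resolved so each domain occurrence is
  reported once. This mirrors how such surveys are actually run — with a
  panel of representative queries rather than a single family consensus —
  and is markedly more sensitive for divergent members: with a single pooled
  AP2 profile the median relative score of genuine domains at 10% target
  divergence is ~0.53, against ~0.83 with per-group profiles.
* **Threshold calibration.** `min_relative_score` defaults to 0.45. This was
  calibrated against both tails: across 1,205 genuine planted domains at 10%
  substitution divergence (five generator seeds) the minimum relative score
  observed was 0.514, while across 2,880 random 300-aa proteins the *maximum*
  window score was −0.121. Any threshold in roughly (0, 0.5) therefore
  separates signal from background; 0.45 leaves margin on both sides. A
  stricter value (for example 0.6) measurably clips genuine divergent domains
  and is only appropriate when near-identity matches are wanted; the
  parameter is exposed everywhere.

The profiles have no insert/delete states: a domain is matched as a fixed
-length window. At desk scale (substitution-only divergence) this is exact;
on real proteomes indel-containing domains would need the threshold lowered
or a profile-HMM tool, which is out of scope and noted as a limitation.

## Gene-model quality control

Automated gene structure predictions of transcription-factor loci are
error-prone, and three rules address the failure modes that matter for a
family catalogue:

* **Long introns.** Any intron strictly longer than `max_intron` (default
  10,000 bp — predicted introns of 8.4 and 35 kb motivated the rule) flags
  the model as unreliable. The flag is informational; the gene stays in the
  catalogue.
* **Fused models.** A protein with ≥ 2 AP2 hits and no B3 hit is either a
  genuine AP2-family gene or a prediction that fused adjacent single-domain
  ERF genes. The decision is delegated to the nearest reference: AP2-family
  nearest → legitimate, no split; ERF nearest → the model is split into one
  product per domain, cutting at the midpoints between adjacent hits.
  Midpoint cutting is deterministic and conservative; template-guided
  boundary refinement against the nearest reference would need curated
  templates and is out of scope.
* **Pseudogenes.** A model whose protein is shorter than `min_protein_len`
  (default 100 aa, well below any single-domain ERF protein) *and* that
  carries at least two introns > 10 kb is flagged as a likely pseudogene and
  excluded from the catalogue. Both conditions are required: short proteins
  alone are often honest fragments, long introns alone are the previous rule.

Splitting conserves domains (the products together carry exactly the fused
model's AP2 domains, one each) and QC is idempotent: run on an already-split
proteome it changes nothing, which the tests assert.

## Neighbor-joining phylogeny

Distances are pairwise-deletion p-distances: per pair, drop alignment columns
with a gap in either sequence, then count mismatches over retained columns.
Equal-length inputs are treated as aligned; ragged inputs are globally
aligned per pair (BLOSUM62), replacing a progressive multiple alignment —
at pairwise-deletion distances the two agree whenever the pairwise
alignments are right, and the tag on the matrix records the method.

Neighbor joining is implemented in-package (the Q-criterion with Saitou–Nei
branch lengths and distance updates). Numerical conventions:

* ties in Q are broken by the lexicographically smallest pair of minimum
  leaf labels, making the topology independent of input order;
* negative branch-length estimates are clamped to 0 and counted
  (`n_clamped`), the common convention when a distance matrix is not
  additive;
* trees are returned as `ape` `phylo` objects (unrooted, $2n-3$ edges), so
  plotting and Newick export use the standard toolchain.

The implementation is verified against exact recovery on additive matrices
(trees with up to 8 leaves), against a brute-force textbook reimplementation,
and against `ape::nj` on random matrices.

Bootstrap support resamples alignment columns with replacement — one shared
column index per replicate, so every pairwise distance within a replicate
uses the same columns — rebuilds the tree, and reports for each internal
edge the percentage of replicates containing the same bipartition (via
`ape::prop.clades`). The conventional 1,000 replicates are the default;
tests use 100 on small alignments, which is enough to saturate
clear splits.

## qPCR expression model

Relative expression is $\Delta Ct = Ct_{HK} - Ct_{gene}$, with $Ct_{HK}$ the
arithmetic mean of the four housekeeping genes in the same sample-replicate;
higher ΔCt means more transcript. Averaging Cts arithmetically is the
log-scale equivalent of geometrically averaging the linear quantities, which
is the standard justification for multi-gene normalizers. A replicate in
which any housekeeping gene is undetected is dropped for all genes in that
condition (with a warning) rather than patched, since a missing normalizer
invalidates the whole replicate.

The ripening fold change is the ΔΔCt: $\log_2 FC = \overline{\Delta
Ct}_{ripe} - \overline{\Delta Ct}_{veraison}$, exact under the efficiency-2
convention (one Ct unit = one doubling). The SD attached to each fold change
is the SD of replicate-wise ΔΔCt values over replicates present at both
stages; with fewer than two such pairs the call is kept but flagged
low-confidence, matching how published tables print fold changes without an
SD. Genes are called up/down at $|\log_2 FC| \ge 2$ (4-fold) by default.

Detectability uses a Ct cutoff of 40 cycles (config-exposed; the platform
convention when no cutoff is published): a gene is detectable if at least one
well anywhere is at or below it. Primer efficiencies, when supplied, are
checked against the inclusive window [1.7, 2.0].

Group over-representation among DEGs uses the one-sided (greater)
hypergeometric tail — Fisher's exact test for enrichment — per group, with
no multiple-testing correction on the reported p (matching the original
analysis, which tested a directed hypothesis per tissue); a
Benjamini–Hochberg column is emitted alongside for modern use. The
implementation is verified against exhaustive enumeration of all
$\binom{N}{n}$ DEG subsets for $N \le 12$ and against `stats::fisher.test`.

Cross-tissue DEG set algebra matches gene names exactly and
case-sensitively. This is deliberate: the published tables themselves are
inconsistent (`VvERF94` in the skin table vs `VvERF094` in the flesh table,
and `VvERF05`), and the bundled fixtures keep the printed strings. Under
exact matching the up-regulated intersection has 3 members, consistent with
the accompanying text; if `VvERF94`/`VvERF094` denote the same gene it would
be 4. The package reports what the tables say and flags the ambiguity here
rather than silently normalizing names.

Expression heat-map ordering uses agglomerative hierarchical clustering
(Euclidean distance on per-condition mean ΔCt vectors, average linkage);
genes with fewer than two non-NA conditions are excluded with a warning, and
genes are sorted by identifier before clustering so the dendrogram does not
depend on input order.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study design: 12 ERF groups, 58-aa AP2
and 50-aa B3 domains, four housekeeping genes, tissues {leaf, stem,
inflorescence, skin, flesh} with veraison/ripe stages for the berry tissues,
and three biological replicates ("at least three" in the emulated design;
three is the minimum consistent with it). Reference panels get 3 members per
group by default; targets are per-site mutated copies of panel members, so
`substitution_rate = 0.05` yields ~95% identity to the source by
construction. Gene models place same-group genes within 50 kb to plant
tandem clusters, and the defect knobs plant fused models (2–3 concatenated
single-domain proteins), one-intron-over-10-kb models, and pseudogenes
(< 100 aa, two introns > 10 kb). Ct tables plant log2 fold changes by
shifting the ripe-stage mean Ct by −f (efficiency 2), draw replicate noise
as N(0, `rep_noise_sd`) with `rep_noise_sd = 0.3` Ct as a realistic
within-run spread, make a configurable fraction of planted up-DEGs come from
one enriched group (default: group IX supplies 50% of 30 planted up-DEGs in
a 120-gene universe where it holds 25% of genes), and emit five genes as
fully undetected.

Passing tests on this generator show that the *pipeline logic* recovers
what was planted: architecture rules, split/exclusion rules, group
assignment, ΔΔCt inversion, enrichment detection. They do not show
performance on real data, where domains contain indels, groups are not
equidistant, qPCR noise is heteroscedastic and efficiency drifts per plate.
The generator deliberately omits codon structure, realistic intron sequence,
and microarray-style data.

## Determinism and problem sizes

Every generator output is a pure function of `sim_config(seed = ...)`
(byte-identical files on repeated runs), and every stochastic analysis step
(bootstrap) takes an explicit seed. The test suite exercises: classification
recovery on 211 genes at 10% substitution (family 100%, group ≥ 95%
required); NJ recovery and oracle agreement up to 8 taxa; Fisher enumeration
up to N = 12; ΔΔCt recovery exactly at zero noise and within 3 standard
errors at 0.3 Ct replicate noise; and enrichment power over 100 simulated
studies (≥ 80 must reach p ≤ 0.05; all 100 do under the default design).
These sizes keep the full suite under a minute while covering every rule
branch; all scale knobs are exposed for larger runs.

## Known limitations

* Fixed-length, ungapped domain windows (no insert/delete states).
* Group assignment is nearest-neighbor only; no phylogenetic placement or
  posterior over groups.
* Split boundaries at inter-hit midpoints, not template-guided.
* Pairwise-deletion p-distances without multiple-hit correction; adequate at
  within-family divergences, increasingly biased beyond ~30% divergence.
* The bundled result-table fixtures inherit the printed tables'
  inconsistencies by design.
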