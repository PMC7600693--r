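---
title: "Methods: quantifying host adaptation of gut Bacteroides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying host adaptation of gut Bacteroides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostadapt)
```

`hostadapt` analyses host adaptation of Bacteroidaceae at three levels:
species abundance across host groups (qPCR), gene content across genomes
(a reference-anchored similarity screen), and gene expression during in
vitro growth (PSM summaries). This vignette describes the models, the
tunable parameters and their defaults, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## The qPCR quantification model

Each sample is assayed in replicate for every species-specific primer pair
and for a pan-bacterial 16S rRNA reference. Replicate Ct values are
averaged per assay, and

$$\Delta C_t = \overline{C_t}(\text{species}) - \overline{C_t}(\text{16S}),
\qquad \text{abundance} = 100 \times 2^{-\Delta C_t}\ \%$$

under the assumption of ideal doubling per cycle: a species one cycle
behind the total-DNA reference makes up 50 % of bacterial DNA, ten cycles
behind ~0.1 %. The formula is the only reading of the quantification under
which abundant species receive high percentages bounded near 100; no
amplification-efficiency correction is attempted (out of scope by design).

**Censoring.** "No amplification" is an explicit censored record (`ct = NA`,
`censored = TRUE`), never a numeric sentinel. A species with all replicates
censored in a sample is *below detection* there. For the rank tests,
below-detection samples enter at the species' minimum detected abundance,
producing ties at the bottom rank — rank tests are insensitive to the exact
value placed there, only to its position. A species detected nowhere is
skipped with a notice.

**Host calls.** Abundances are compared across host groups with the
Kruskal–Wallis test; when significant at α (default 0.01 for host calls,
0.05 elsewhere), Dunn's post hoc test (Holm-adjusted by default; the
adjustment is configurable because the choice is a convention, not part of
the model) must place the top-median host significantly above *every* other
host before the species is labelled adapted to it. Otherwise the call is
"no significant host signal".

## Rank tests

The package implements the tie-corrected Kruskal–Wallis H, Dunn's z on
pooled mid-ranks, and the Mann–Whitney U directly, because it needs exact
small-sample p-values with tie handling:

* **Mann–Whitney:** U from mid-ranks; for $n_x + n_y \le 16$ the two-sided
  p is the exact proportion of all $\binom{n}{n_x}$ relabellings whose U is
  at least as far from $n_x n_y / 2$ as observed (ties included naturally,
  since permutation operates on the observed multiset). Larger samples use
  the tie-corrected normal approximation with continuity correction, and
  the output flags which path ran.
* **Kruskal–Wallis:** chi-square reference when every group has ≥ 5
  observations; otherwise exhaustive enumeration of group assignments (up
  to 2 × 10^5 arrangements) or seeded Monte Carlo. `p_method` can force a
  path.
* **Dunn:** $z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)\,
  (1/n_i + 1/n_j)}$ with the usual tie term $T$, two-sided normal raw p,
  then `p.adjust`.

The test suite checks all three against brute-force enumeration oracles on
every random input with total n ≤ 10, and against `kruskal.test` /
`wilcox.test` where those are applicable. The type-I-error check runs at
30 observations per group: the chi-square reference is asymptotic, and
the check's purpose is to validate the implementation rather than the
approximation — at small n the package switches to permutation p-values
anyway.

## The similarity screen

Protein similarity is global (Needleman–Wunsch) alignment percent identity
under BLOSUM62 with affine gaps (open 11, extend 1):
`100 × identical columns / (alignment length − terminal gap columns)`.
Internal gaps count against the denominator; terminal overhangs do not, so
a truncated but otherwise identical protein still scores 100. The measure
is symmetric and deterministic. Identity (not substitution-matrix
"positives") is used; the scoring scheme is recorded in output metadata.
The implementation reads the identical-column count and terminal-trimmed
length directly from the alignment object; a test verifies this against
explicit column-by-column bookkeeping on the aligned strings.

A presence matrix anchors on one reference genome (default: the
lexicographically first in-group genome): each reference gene's best hit
per genome classifies as

| category | similarity |
|---|---|
| `absent` | < 50 % |
| `present_divergent` | 50–99 % (inclusive at both ends) |
| `present_recent_transfer` | > 99 % |

The lower bound is inclusive because published screens of this design count
cells of exactly 50 as present. Host-specific genes must be present in
*every* in-group genome and absent from *every* out-group genome — the
strict reading, which matrices of real screens support.

**Transfer candidates and islands.** Within one host group, genes pairwise
more than 99 % identical are clustered by single linkage; a cluster whose
distinct carrier set has size k with `min_carriers ≤ k ≤ group size − 1`
(defaults 3 and group−1: present in several genomes but not all, the
signature of recent horizontal acquisition rather than vertical descent) is
a transfer candidate. Candidate pairs are pre-screened by shared exact
12-mers before alignment; two proteins above 99 % identity at biological
lengths always share such a seed, so the prefilter cannot lose true pairs.
Candidates with identical carrier sets whose genes occupy consecutive
positions in every carrier (whole-run reversal allowed — strand is not
modelled at the protein level) merge into maximal runs; runs of length ≥ 2
are genomic islands. The output is a partition: no gene sits in two
islands.

**Gene families.** Genes group by normalised function label (case-folded,
whitespace-collapsed). A family is retained when at least one genome
carries ≥ 10 members; the per-"every genome" reading is available via
`require_in_every_genome = TRUE`, but the lenient default is deliberate —
requiring 10 in every genome would silently drop exactly the families
absent from one host group, which are the signal of interest. Retained
families and genome sizes are contrasted with the exact Mann–Whitney test;
family p-values are raw by default (matching the conventions of the screens
this reproduces), with `p.adjust` available downstream.

## Proteome summaries

PSM tables are `(protein, strain, condition, count)` records, with
technical LC-MS replicates assumed pre-summed. `n_expr` counts
strain × condition cells with ≥ 1 PSM — for 5 strains and 11 conditions
(inoculum + 5 media × 2 subcultures) the maximum is 55 — and renders 0 as
"n.e." on output only. Relative abundance is the protein's share of total
PSM within each strain-condition (summing to 100 % per cell); the
per-protein mean averages over all cells in the table, counting absent
cells as zero. Averaging including zeros is a choice (the alternative,
averaging only over detected cells, inflates rarely seen proteins); it is
stated in the output metadata.

## The synthetic-data generator

`simulate_genomes()` emulates the genome structure the screen assumes, with
substitution-only divergence over the 20-letter amino-acid alphabet so the
planted similarity relationships are analytically controllable (two copies
at divergence d from a common ancestor are ≈ 100(1−d)² % identical):

* **Core families** (default 30 per genome, 60–100 residues) descend from
  per-family ancestors at `within_group_divergence` (default 0.08 →
  ≈ 85 % pairwise identity) in *every* genome, so cross-group similarity
  stays above 50 % and core genes are never mistaken for host-specific
  ones.
* **Host-A-specific families** (default 5) are intact in every group-A
  genome but present in group B only as remnants diverged through an
  intermediate ancestor at `between_group_divergence` (default 0.7 →
  ≈ 25 % cross-group identity, safely below the absence threshold).
* **Transfer genes** (default 8) are verbatim copies in exactly
  `transfer_carrier_count` (default 3) group-B genomes — verbatim because
  the transfer category is strictly > 99 % and a single substitution in a
  ~100-residue gene already drops a pair to ≈ 99 %. The first 5 occupy a
  consecutive block in every carrier (the island); the rest are placed so
  that no two planted genes are ever adjacent, making the island the unique
  syntenic run.
* **Genome sizes** draw from the contrasting ranges characteristic of the
  two lineages: 4.23–6.70 Mb (group A / human-adapted) vs 3.43–4.46 Mb
  (group B / chicken-adapted), seven genomes per group.

`simulate_ct_table()` inverts the quantification model:
`Ct(species) = baseline − log2(p/100) + ε`, `Ct(16S) = baseline + ε`, with
ε Gaussian per replicate (the simplest model consistent with duplicate
PCR; no published noise model exists for Ct duplicates, so Gaussian is an
assumption of the generator, not an inference). Defaults: 20 samples per
host, duplicate reactions, noise sd 0.3 Ct, and a 100-fold reciprocal
abundance contrast (10 % vs 0.1 %) between two species across two hosts.
With zero noise the round trip is exact to floating precision.

`simulate_psm_table()` zeroes each cell with probability `sparsity` and
otherwise draws `1 + Poisson(mean_psm − 1)`, so the zero fraction equals
the sparsity parameter exactly in expectation and detected cells are
always ≥ 1.

All three generators take a single integer seed and restore the caller's
RNG state; same seed, same output, byte for byte.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: insertions/deletions and codon-level
evolution (real alignments gap; the identity measure handles gaps but the
planted truth never exercises them heavily), paralogy and gene family
expansion within a genome, annotation noise in function labels,
amplification-efficiency differences between primer pairs, and
compositional or phylogenetic signal. Recovery of planted signals shows the
screening logic is correct at its thresholds, not that 50 %/99 % are
optimal for any particular dataset.

## Numerical and design notes

* Problem sizes in the tests and the acceptance script: 14 genomes × ~35
  genes of 60–100 residues for the planted-recovery screen, 200 seeded
  replicates for host-call accuracy, 10,000 for the type-I rate — sizes at
  which every check runs comfortably on a laptop while the planted effects
  remain unambiguous.
* Ties everywhere are broken deterministically (assay name order, lowest
  gene order index, protein id), so identical inputs give identical
  outputs.
* Similarity of an alignment with no non-terminal columns is defined as 0
  (avoids 0/0 on degenerate pairs).
* Abundances above 100 % (species assay crossing before the 16S reference)
  are possible in noisy data; they are kept but flagged with a warning.
* A published 29-gene screen ships as `inst/extdata/human_specific_genes.tsv`
  for fixture-level checks; 24 of its rows carry numeric expression counts
  and five are "n.e.". The most abundant protein is glutamate decarboxylase
  at 1.05 % of total protein.

## Limitations

Single-reference anchoring means genes absent from the chosen reference are
invisible to the screen (a pan-genome graph is out of scope). The HGT
call is purely identity-threshold-based: it cannot distinguish very recent
vertical inheritance within a clonal cluster from transfer, and does no
tree reconciliation. The proteome module starts from PSM counts;
everything upstream (search engine, FDR control, protein inference) is
taken as given.
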