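---
title: "Codon usage bias analysis with cubkit: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon usage bias analysis with cubkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubkit)
```

## The problem

Because the genetic code is degenerate, a protein fixes only part of its
coding sequence: most amino acids can be spelled by two to six synonymous
codons, and real genes use them unevenly. This codon usage bias (CUB) is
shaped by two forces — directional mutation pressure, which pushes all
three codon positions toward the same nucleotide pool, and selection
(translational or structural), which acts on the codon choice itself and
decouples the silent third position from the amino-acid-constrained first
two. cubkit implements the standard battery of statistics used to survey
CUB in a gene set (for example a disease-associated gene panel): per-gene
composition, the effective number of codons, relative synonymous codon
usage, the codon adaptation index, protein-level GRAVY and aromaticity,
the neutrality and parity-rule-2 diagnostics, correspondence analysis of
the gene-by-codon RSCU matrix, neighbor-joining clustering of RSCU
profiles, and codon-pair context classification.

## Input gate

Sequences enter through a strict CDS gate: a valid gene is a multiple of
3 bases, starts with an initiation codon (`ATG` by default; alternative
starts are admitted by option), ends with a stop, contains no internal
stop and no ambiguous base, and carries at least `min_codons` (default
30) sense codons. All applicable failure codes are reported, and failing
genes are excluded from every downstream table unless the permissive
override is chosen. Under the permissive policy, codons containing `N`
are dropped from counts rather than failing the gene.

## The statistics

**ENc.** For each synonymous family the homozygosity
$F = (n\sum p_i^2 - 1)/(n-1)$ (Wright's bias-corrected form; a plugin
$\sum p_i^2$ variant is selectable) estimates the probability that two
codons of the family coincide. Averaging within the 2-, 3-, 4- and
6-fold degeneracy classes gives
$N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
capped into $[20, 61]$. Numerical choices the literature leaves open:
families with fewer than 2 counts are skipped; corrected estimates
$F \le 0$ (possible at counts like (1,1)) are also skipped because their
reciprocal is undefined; a degeneracy class with no usable family is
imputed as $1/k$ shifted by the mean deviation of the observed classes
(a plain $1/k$ fallback is selectable). The cap matters: under exactly
uniform usage the corrected estimator exceeds 61 at finite counts.

**RSCU.** $\mathrm{RSCU}_i = k\,n_i/\sum_{j\in\text{family}} n_j$; values
within a family sum to the family size. Codons with RSCU > 1.6 are
classed over-represented and < 0.6 under-represented. The classification
universe is the 59 degenerate sense codons; Met and Trp are carried at
RSCU = 1 but never classified, which reconciles the conflicting 59/60
codon conventions in the survey literature.

**CAI.** The geometric mean of relative adaptiveness weights
$w_i = n_i / \max_{\text{family}} n$ over the counted degenerate codons.
The reference table is user-suppliable; the self-contained default
derives weights from the pooled counts of the 10% of input genes with
the lowest ENc (the most biased genes stand in for a high-expression
reference, keeping the pipeline free of external downloads). Zero-count
reference codons are floored at $w = 0.01$ with a warning to keep the
log-domain mean finite.

**Neutrality plot.** OLS regression of GC12 (mean GC at positions 1 and
2) on GC3, with Pearson r and a two-sided p. OLS rather than reduced
major axis because the quantity of interest is the directional
regression of GC12 *on* GC3. A constant GC12 yields slope 0 and, by
convention, r = 0 and p = 1 (the Pearson coefficient is formally 0/0
there). "GC3" throughout the package is the synonymous-position measure
(GC3s): third positions of the 59 degenerate codons only, the CodonW
convention.

**PR2.** Each gene maps to $x = A_3/(A_3+T_3)$, $y = G_3/(G_3+C_3)$; a
zero denominator is reported as undefined, never silently 0. Two
third-position universes are supported. The default (`"synonymous"`,
all 59 degenerate codons) matches the rest of the package; note that in
this universe even a perfectly strand-symmetric mutation process does
*not* sit at (0.5, 0.5), because the stop codons remove the A/G-ending
partners of the Tyr and Cys families — tallying third bases over the 59
codons gives A = 14, T = 16, G = 13, C = 16, so the null point is
roughly (0.467, 0.448). The `"fourfold"` convention (third positions of
the five 4-fold families only, the original parity-rule universe) is
exactly symmetric, and the package's symmetry tests use it.

**Correspondence analysis.** Chi-square-metric CA of the gene x 59-codon
RSCU matrix (rows are genes, as in CodonW): grand-total normalisation,
standardised residual matrix
$S = D_r^{-1/2}(P - rc^{\mathsf T})D_c^{-1/2}$, SVD, and principal
coordinates, so axis variances equal per-axis inertias. Axis signs are
canonicalised by making the largest-magnitude codon loading positive;
SVD leaves them arbitrary otherwise. All-zero rows/columns (codons unused
in every gene) are dropped with a warning since their chi-square profiles
are undefined. Genes with an empty family contribute RSCU 0 for those
codons in the matrix.

**Clustering.** Neighbor joining on Euclidean distances between RSCU
vectors — the agglomeration method is the one named in the survey
tradition; the metric is the simplest defensible default and is
configurable. Ties in the Q criterion are broken toward the
lexicographically first label pair; a negative branch length is clamped
to zero with the deficit moved to its sibling so path lengths through the
join are preserved. The output is an unrooted tree with a basal
trichotomy, serialised as newick.

**Codon-pair context.** Adjacent in-frame sense-codon pairs are pooled
across genes into a 61 x 61 table (pairs never cross gene boundaries and
never involve the terminal stop). Expectations come from the
independence model $e_{ij} = r_i c_j / n$ and cells are scored by the
adjusted standardised residual
$(o-e)/\sqrt{e\,(1-r_i/n)(1-c_j/n)}$, approximately N(0,1) under
independence. A pair is over-/under-represented at $|$residual$| \ge 3$
(configurable), absent iff never observed; cells with expectation below
1 are never called over/under because the normal approximation fails
there, and such exclusions are tallied in a warning.

## The synthetic-data generator

The generator is first-class, tested code: it provides gene sets with
known ground truth for every pipeline stage.

* `mutation_only` — every position of a gene drawn i.i.d. from one
  GC-parameterised pool (GC drawn per gene from `gc_range`, default
  0.3-0.7). GC12 and GC3 then share a single driver, so the neutrality
  slope is ~1 by construction.
* `selection` — amino acids drawn from a fixed vertebrate-like
  composition (GC12 pinned), synonymous codons chosen with third-base
  probabilities tilted to a per-gene GC3 drawn from `gc3_range` (default
  0.3-0.9). GC3 varies while GC12 barely moves: slope ~0.
* `mixed` — positional pools with partial coupling
  (`gc12 = 0.48 + 0.4 (gc3 - 0.6)` by default), emulating a real gene
  set where both forces act.
* a first-order codon chain with configurable pair enrichments provides
  positive controls for the pair-context classifier.

The `ec_like_spec()` preset states the emulated world once: 82 genes,
sense lengths 300-3000 codons, mixed regime, overall GC near 0.52,
per-gene GC3 spanning 0.3-0.9 — the character of a GC-rich human
disease-gene panel. Determinism: one integer seed; each gene's draws
come from a substream fixed by (seed, gene index), so sets are
reproducible byte-for-byte and insensitive to generation order.

Two numerical honesty notes. Stop codons are avoided by rejection
sampling, which conditions the positional model on "not a stop" and
shifts expected GC by up to ~0.015 from the raw pool value; the
ground-truth table therefore records the closed-form conditional
expectation, so recovery checks compare like with like. And realized GC
is a binomial average — at 500 codons its standard deviation is ~0.013,
so per-gene bands tighter than ~3 sigma are meaningless; the test suite
checks tracking distributionally (tight mean deviation, a 0.02 band for
most genes, a 6-sigma cap) at 2000-3000 codons.

What a green test does **not** establish: the generator has no codon
autocorrelation beyond the engineered pair chain, no length-composition
dependence, no amino-acid-level selection, no isochore structure and no
splicing artefacts — all present in real human genes. Agreement on
synthetic data certifies the statistics, not biological conclusions.

## Design choices where the ground was open

* Initiation codon: `ATG` only by default, extendable — the strictest
  reading of "proper initiation".
* Skews (`(A-T)/(A+T)`, `(G-C)/(G+C)`) are computed on the coding strand
  excluding the terminal stop; reverse *complementation* negates them
  (reversal alone does not — it preserves base counts).
* Correlation matrices default to Pearson (Spearman by flag); constant
  columns yield NA with a warning rather than an error, and the pipeline
  reports Benjamini-Hochberg adjusted p-values alongside raw ones.
* The pipeline is a pure function of (inputs, configuration); the JSON
  manifest records input digests and per-stage row counts so reruns can
  be certified byte-identical.

## Known limitations

ENc variants differ across published implementations in their handling
of rare families; both estimators here are documented above and exposed,
but exact numeric agreement with any particular legacy tool (CodonW,
Acua, INCA) on edge-case genes is not guaranteed. CAI depends entirely
on the reference weights; the lowest-ENc-decile default is a pragmatic
stand-in, not a validated expression reference. The pair-context
classifier tests marginal independence only — it cannot distinguish
dicodon selection from amino-acid-pair composition effects.
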