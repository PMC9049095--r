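# cubkit — codon usage bias analysis of coding sequences

Synonymous codons are not used interchangeably: mutation pressure and
selection leave characteristic fingerprints in which codons a gene set
prefers. `cubkit` is an R package for surveying that bias in any set of
protein-coding sequences (a disease-associated gene panel, a pathway, a
small genome): it validates CDSs, computes the field's standard
statistics, runs the two classic mutation-vs-selection diagnostics,
ordains and clusters the genes, classifies adjacent codon-pair context,
and ships a synthetic CDS generator so every stage is testable without
downloading anything.

## What it computes

| Statistic | Definition |
|---|---|
| ENc | Wright's effective number of codons, `Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆` from per-family homozygosities `F = (nΣp² − 1)/(n − 1)`, capped into [20, 61] |
| RSCU | `k·nᵢ/Σn` per synonymous family; > 1.6 over-represented, < 0.6 under-represented |
| CAI | geometric mean of relative adaptiveness weights `wᵢ = nᵢ/max n` over degenerate codons |
| GRAVY, aromaticity | mean Kyte–Doolittle hydropathy; fraction of Phe/Tyr/Trp |
| Neutrality plot | OLS of GC12 on GC3(s): slope ≈ 1 ⇒ mutation pressure, ≈ 0 ⇒ selection |
| PR2 plot | `A3/(A3+T3)` vs `G3/(G3+C3)` at synonymous (or 4-fold) third positions; (0.5, 0.5) = parity |
| COA | chi-square correspondence analysis of the gene × 59-codon RSCU matrix, principal coordinates, per-axis inertia |
| NJ tree | neighbor joining on Euclidean RSCU distances, newick output |
| Codon-pair context | 61 × 61 observed/expected/adjusted-residual table; over / under / absent / typical at \|residual\| ≥ 3 |

## Worked example

```r
library(cubkit)

# a synthetic stand-in for a GC-rich 82-gene disease panel
genes <- generate_cds_set(ec_like_spec(seed = 1))
write_fasta(genes, "ec82.fasta", truth_path = "ec82_truth.tsv")

res <- run_all(run_config("ec82.fasta", "ec_run", seed = 1))
summarize_run("ec_run")
```

prints (output of this exact code):

```
genes analysed: 82
ENc: mean 53.77 +/- 6.75, range 37.40-61.00
overall GC: 52.60%
CAI: range 0.268-0.806
top RSCU codons: CCG (1.32), GCC (1.30), CCC (1.30)
bottom RSCU codons: GGT (0.70), GCT (0.70), CCT (0.68)
neutrality slope 0.3809 (r = 0.988, p = 4.85e-66, n = 82)
PR2 means: A3/(A3+T3) = 0.4646, G3/(G3+C3) = 0.4452
COA inertia: axis 1 78.1%, axis 2 2.1%
codon pairs: 2.42% over, 1.13% under, 0.00% absent
```

Reading it: ENc spans weakly to moderately biased genes (61 = no bias,
20 = one codon per amino acid); overall GC ≈ 52% matches the preset's
stated world; the neutrality slope of 0.38 reflects the mixed regime's
partial coupling of GC12 to GC3 (a pure-mutation set gives ≈ 1, a
pure-selection set ≈ 0); GC-ending codons (CCG, GCC, CCC) top the pooled
RSCU ranking as expected for a GC-rich set; and with no engineered
dicodon preferences almost no codon pair deviates from independence.

`run_all()` writes one TSV per stage (`qc.tsv`, `composition.tsv`,
`gene_metrics.tsv`, `rscu_pooled.tsv`, `correlation.tsv`,
`neutrality.tsv`, `pr2.tsv` + summary, `coa_*.tsv`, `tree.nwk`,
`codon_pairs.tsv` + summary/heat-map grid) plus `manifest.json` with
input digests and row counts; reruns are byte-identical.

The same pipeline is scriptable from the shell:

```sh
Rscript inst/scripts/cubkit simulate --preset ec-like --seed 1 --outdir data
Rscript inst/scripts/cubkit run-all --input data/synthetic.fasta --outdir out
Rscript inst/scripts/cubkit summarize --indir out
```

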