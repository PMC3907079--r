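# descna

Dosage effect scoring for paired copy-number / expression tumor cohorts.

## The problem

Somatic copy-number alterations (CNAs) are pervasive in cancer, but a gene
whose locus is amplified or deleted does not necessarily change its mRNA
output: some genes are *dosage sensitive* (expression tracks copy number),
others are *dosage resistant* (expression is buffered). `descna` quantifies
this per gene, for cohorts where each sample has both an expression profile
and a copy-number profile — the motivating setting is multiple myeloma,
whose hyperdiploid subtype carries trisomies of chromosomes 3, 5, 7, 9, 11,
15, 19 and 21, while the non-hyperdiploid subtype is enriched for
chromosome 13 deletion.

## The score

For gene *g* in a cohort of *n* samples, with linear-scale copy number
(diploid = 2):

- a sample is a **loss** if CN < 1.7, a **gain** if CN > 2.3, otherwise
  **copy-neutral** (the band absorbs noise and normal-cell contamination);
- from the copy-neutral samples compute the expression mean μ and standard
  deviation σ;
- a CNA sample is **concordant** when its expression exceeds μ + σ (gain)
  or falls below μ − σ (loss);
- the **dosage effect score** is

  DES(g) = #concordant samples / #CNA samples ∈ [0, 1],

  defined only when the CNA count exceeds 10 % of the cohort (and at least
  5 copy-neutral samples with σ > 0 exist).

Genes with DES > 0.4 are called dosage sensitive; highly expressed genes
(top 20 % by median expression) with DES < 0.2 are dosage resistant.
Around the score the package provides hyperdiploidy calling (median
trisomy-chromosome CN, bimodal cutoff 2.3), SNP→gene copy-number
summarization (mean over SNPs within 5 kb of the transcript), moderated
differential expression with Benjamini–Hochberg control, Fisher-exact
gene-set enrichment, a Cochran–Armitage trend test across expression
quintiles, a genome-wide karyotype plot, and a synthetic cohort generator
with planted ground truth.

## Worked example

```r
library(descna)

sim  <- simulate_cohort(sim_config(n_samples = 60, n_genes = 300, seed = 7))
calls <- classify_ploidy(sim$dataset)
table(calls$label)
#>  HMM NHMM
#>   27   33

des <- compute_des(sim$dataset)
sum(!is.na(des$des))
#> [1] 143

ev <- truth_eval(des, sim$truth)
round(c(auroc = ev$auroc, sensitive = ev$mean_des_sensitive,
        resistant = ev$mean_des_resistant), 3)
#>     auroc sensitive resistant
#>     0.972     0.444     0.170
```

60 samples are split into hyperdiploid (HMM) and non-hyperdiploid (NHMM)
by their median trisomy-chromosome copy number. 143 of 300 genes sit in
regions altered often enough (> 10 % of samples) for a defined DES. The
planted dosage-sensitive genes average DES ≈ 0.44 versus ≈ 0.17 for
resistant genes, and DES ranks sensitivity with AUROC ≈ 0.97.

On file inputs, the same analysis is one call:

```r
res <- run_pipeline(expression = "expr.tsv", copy_number = "cn.tsv",
                    annotation = "genes.tsv", out_dir = "out")
```

which writes the DES table, ploidy calls, differential expression,
per-chromosome summaries, both figures and a `manifest.json`. A thin
command-line wrapper with the same subcommands (`simulate`, `gene-cn`,
`ploidy`, `des`, `diffexp`, `enrich`, `plot-karyotype`, `plot-dist`,
`run`) lives at `inst/cli/descna.R`.

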