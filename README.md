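# mirActivity

Infer per-sample or per-cell **miRNA activity from mRNA expression
alone**. Single-cell RNA-seq protocols capture polyadenylated mRNA and
therefore miss miRNAs entirely; bulk cohorts often lack matched small-RNA
libraries. But an active miRNA leaves a footprint on the mRNA side: genes
whose 3'UTR carries the 7-mer complementary to the miRNA seed (mature
positions 2–8) are shifted toward repression. This package quantifies
that shift, sample by sample, and reports a signed activity score per
miRNA. It is aimed at transcriptomics analyses — bulk cohorts or
single-cell experiments — where miRNA regulation matters but miRNA
expression was never measured.

## Method in brief

For each sample *s*, relative expression is computed against the
within-data-set surrogate control

&nbsp;&nbsp;&nbsp;&nbsp;Δe<sub>gs</sub> = e<sub>gs</sub> − median<sub>s'</sub>(e<sub>gs'</sub>),

genes are ranked by Δe (most repressed first), each gene carries a motif
indicator I<sub>g</sub> and a sequence-specific null probability
p<sub>g</sub> = P(≥1 motif occurrence in a random sequence matching the
UTR's length and base composition), computed exactly by Markov-chain
embedding of the motif's string-matching automaton. The default
statistic is the **modified rank sum**: with centered rank weights
c<sub>g</sub> = (N+1)/2 − r<sub>g</sub>,

&nbsp;&nbsp;&nbsp;&nbsp;T = Σ<sub>g</sub> c<sub>g</sub>(I<sub>g</sub> − p<sub>g</sub>),&nbsp;&nbsp;
Var = Σ<sub>g</sub> c<sub>g</sub>² p<sub>g</sub>(1 − p<sub>g</sub>),&nbsp;&nbsp;
Z = T/√Var,

and the activity score is **−log10(p) · sign(Z)** — positive when target
motifs concentrate among repressed genes. Subtracting p<sub>g</sub>
cancels UTR length/composition bias that inflates a naive rank-sum test.
Alternatives: a Brownian-bridge maximal-deviation statistic (`bb`), a
hypergeometric landscape scan over ranking cutoffs (`hypergeom`), and a
rank-sum test on curated target sets (`tarbase`). See the methods
vignette (`vignettes/mirna-activity-inference.Rmd`) for the statistics,
numerical choices and limitations.

## Worked example

Everything runs on synthetic data with known ground truth — no reference
downloads. The generator plants one miRNA whose targets are repressed by
δ log2 units in a subset of "active" cells:

```r
library(mirActivity)

fx <- generate_fixture(n_genes = 500, n_cells = 60, n_mirnas = 8,
                       n_targets = 80, n_active = 30, delta = 1, seed = 7)
act <- mir_activity(fx$counts, fx$utrs, fx$mirnas, layer = "counts")
dim(act)
#> [1] 60  9     # 60 cells x (8 miRNAs + opposite-strand decoy)

planted <- fx$truth$planted_mirna   # "syn-miR-1-5p"
active  <- fx$truth$active_cells
mean(act[active,  planted])   #>   8.05
mean(act[!active, planted])   #> -10.31
```

The planted miRNA scores strongly positive in active cells (motif genes
enriched among that cell's repressed genes) and negative in inactive
cells (relative to the cross-cell median, the same genes sit high there),
while the seven background miRNAs stay near 0 (mean 0.00). The score is
a faithful proxy for the planted activity state:

```r
activity_expression_correlation(act[, planted], as.numeric(active))
#> $r  0.91      $p  6.75e-24
```

Read-depth sensitivity (`depth_sweep`), cell-type outlier scoring
(`celltype_specificity`) and the individual statistics (`mrs_test`,
`bb_test`, `hypergeom_landscape`, `targetset_ranksum`) are exported with
the same containers. A command-line front end covering the whole
workflow lives at `inst/cli/miract.R`:

```sh
Rscript inst/cli/miract.R fixtures --out fx --seed 3
Rscript inst/cli/miract.R activity --utrs fx/utrs.fa --mirnas fx/mirnas.fa \
    --expr fx/counts.tsv --method mrs --out run
```

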