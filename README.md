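# tadloop

Differential analysis of 3D genome organization between two Hi-C
conditions — for example 2D monolayer versus 3D spheroid cultures of the
same cell line. Given processed Hi-C inputs (binned contact matrices in the
HiC-Pro dialect, three-state TAD calls, significant-interaction-fragment
tables, a gene annotation and a differential-expression table), `tadloop`
answers two questions a chromatin-biology analyst asks when comparing
conditions:

* **How did the domain landscape change?** TADs of the two conditions are
  matched by overlap and every TAD is assigned to one of eight change
  events — no change, conserve-expand, conserve-shrink (together
  "relatively conserved", RC), and shift, split, fuse, neo, del
  ("drastically changed", DC) — using a 300 kb conserve bound.
* **Which genes changed their looping?** A promoter–distal (P1D1) loop is a
  significant interaction with one anchor on a gene's promoter
  (−4 kb/+1 kb of the 5'TSS) and the other on the same gene's distal
  region (10–100 kb from the TSS), with promoter-priority anchor
  assignment. Each loop is scored in valid pairs per million,

  VPPM = (valid pairs within the loop / total valid pairs) × 10⁶,

  summed per gene; the per-gene VPPM difference between conditions is
  normalized to [0, 1] and genes scoring ≥ 0.15 are strengthened looping
  genes (SLGs). SLGs that also pass the DEG filter
  (|log2FC| ≥ 0.58, p ≤ 0.05) are differentially expressed looping genes
  (DELGs).

The package also provides LOWESS inter-sample bias normalization of contact
matrices with distance-decay/correlation diagnostics and binomial
down-sampling, a synthetic-data generator that emits every input dialect
with known ground truth, and an end-to-end pipeline driver with a YAML
config and a CLI wrapper (`inst/scripts/tadloop-cli.R`).

## Worked example

Simulate the default two-condition scenario (one 20 Mb chromosome, 40 kb
bins, 60 genes, one planted TAD-change event of each type, 5% of genes with
5-fold strengthened loops) and run each stage:

```r
library(tadloop)

spec   <- scenario_spec(seed = 1)
genome <- simulate_genome(spec)
pair   <- simulate_domain_pair(spec, genome$layout)

summarize_changes(classify_changes(pair$a, pair$b))
#>             type count fraction
#>        no_change     1    0.125
#>  conserve_expand     1    0.125
#>  conserve_shrink     1    0.125
#>            shift     1    0.125
#>            split     1    0.125
#>             fuse     1    0.125
#>              neo     1    0.125
#>              del     1    0.125
#> RC fraction 0.375, DC fraction 0.625 over 8 events

sifs <- simulate_sif_tables(genome$genes, spec)
la <- call_p1d1_loops(sifs$sif_a, genome$genes, spec$depth, sample_id = "cond_a")
lb <- call_p1d1_loops(sifs$sif_b, genome$genes, spec$depth, sample_id = "cond_b")
la
#> looping_gene_table 'cond_a': 89 P1D1 loops over 56 looping genes; total valid pairs 2e+06

strengthened_looping_genes(la, lb)
#> slg_result: 6 strengthened in 'cond_b', 13 in 'cond_a' (cutoff 0.15, policy pooled_z_minmax) over 60 genes
```

All eight planted change types are recovered exactly (the RC fraction
3/8 = 0.375 is the share of no-change/expand/shrink events); 89 of the
planted promoter–distal SIFs in condition A become loops over 56 looping
genes, and the strengthened set in condition B contains the genes whose
loops were planted at higher strength. The whole chain — including LOWESS
normalization, loop partitioning, and the DEG intersection — runs as one
deterministic command:

```r
report <- cmd_run_all(list(seed = 1), "out")   # writes out/report.json
```

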