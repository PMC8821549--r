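# trbound

Consensus ChIP-Seq identification of thyroid hormone receptor (TR)
target genes.

## The problem

Thyroid hormone (T3) remodels organs during postembryonic development —
most visibly during amphibian metamorphosis — by switching its nuclear
receptors TRα/TRβ, already sitting on T3 response elements (TREs) in
chromatin, from repressors to activators.  Identifying *direct* TR
target genes in a remodeling tissue takes a replicated ChIP-Seq
experiment and a chain of analyses: which regions are reproducibly
bound, which genes they belong to, whether they carry the canonical
DR4-type TRE, how binding overlaps T3-regulated expression, and which
bound-gene programs are lost in a TRα knockout.  `trbound` implements
that chain for R users, together with a seeded synthetic-study
generator so every stage can be validated against known ground truth.

## What it computes

* **Replicate-consensus peaks** (`intersect_replicates`) — maximal
  genomic runs covered by ≥ 1 peak in *every* replicate of a sample
  (per-base definition; 0-based half-open coordinates).  The consensus
  height is min over replicates of the max contributing height.  A
  simplified Poisson pileup caller (`pileup_call`) handles synthetic
  fragment tracks: per-base coverage vs a Poisson(background × mean
  fragment length) null, Benjamini–Hochberg adjusted across the genome.
* **Peak-to-gene assignment** (`build_windows`, `assign_peaks`,
  `bound_gene_set`) — a peak is assigned to every gene whose gene body
  (introns included) ± 5 kb flank it overlaps by ≥ 1 base; the TR-bound
  gene set is the union over peaks.
* **DR4 TRE scanning** (`scan_dr4`, `count_tres_in_peaks`) — direct
  repeats of the (A/G)GGTCA half-site separated by 4 unconstrained
  bases, both strands, all overlapping occurrences.
* **Set analytics** (`select_regulated`, `venn`, `overlap_percent`,
  `partition_by_genotype`, `fold_change_matrix`) — regulated-gene
  selection at 1.5-fold (inclusive, log2 scale) with FDR < 0.05
  (strict); exact Venn region cardinalities; integer percentages
  rounded half away from zero.
* **Term enrichment** (`hypergeom_p`, `bh_fdr`, `enrich`,
  `differential_enrichment`) — one-sided hypergeometric test with
  BH-FDR over user-supplied GMT annotations, and the genotype
  "subtraction": terms enriched among wild-type-bound genes but not
  among knockout-bound genes.
* **Synthetic studies** (`sim_config`, `simulate_tr_chipseq`,
  `evaluate_recovery`) — 2 genotypes × 2 treatments × 3 technical
  replicates with planted DR4-bearing sites, boundary jitter, dropouts,
  false peaks, knockout-attenuated binding and linked expression;
  byte-identical outputs per seed, plus precision/recall evaluation
  against the truth record.
* **Orchestration** (`run_tr_pipeline`) — all stages in order with
  pre-flight input checks, per-stage TSV/BED outputs and a
  `report.json`.

## Worked example

Simulate a small four-sample study and run the full pipeline:

```r
library(trbound)
cfg <- sim_config(seed = 42, n_chroms = 1, chrom_length = 700000L,
                  n_genes = 50, n_true_sites = 60)
sim <- simulate_tr_chipseq(cfg, dir = "demo")
report <- run_tr_pipeline(
  peak_files = lapply(sim$paths$peaks, unname),
  gff3 = sim$paths$annotation,
  fasta = sim$paths$genome,
  expression = sim$paths$expression,
  out_dir = "demo_run")
print(report)
```

```
TR target-gene pipeline report
  WT_minusT3      40 consensus peaks,    24 bound genes
  WT_plusT3       54 consensus peaks,    32 bound genes
  KO_minusT3      30 consensus peaks,    18 bound genes
  KO_plusT3       40 consensus peaks,    25 bound genes
  WT union: 34 bound genes
  genotype partition: wt_only 10 | common 24 | ko_only 2
  18% of bound genes T3-upregulated
```

Reading the report: each sample's ~20k-style replicate peak calls
collapse to the regions supported by all three replicates (40–54 here);
those regions map into gene-body ± 5 kb windows, giving per-sample
bound-gene sets; +T3 samples recover more sites than −T3 (the
treatment-dependent margin over the constitutive core), and the
knockout retains most but not all wild-type binding (common 24 of the
34 wild-type-bound genes, with 2 knockout-only).  18% of bound genes
are T3-upregulated — the generator's linkage probability was 19%.
Recovery against the truth record:

```r
evaluate_recovery(sim$truth, lapply(sim$peaks, intersect_replicates))
#>    sample_id n_true n_called site_precision site_recall
#> 1 WT_minusT3     46       40              1   0.8695652
#> 2  WT_plusT3     60       54              1   0.9000000
#> 3 KO_minusT3     36       30              1   0.8333333
#> 4  KO_plusT3     47       40              1   0.8510638
```

Precision is 1 — independent false peaks almost never co-occur in all
three replicates — while recall sits near (1 − dropout)³ ≈ 0.86, the
survival probability of a site through three independent 5% dropouts.

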