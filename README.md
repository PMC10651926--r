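# dnbtip

Dynamic network biomarker (DNB) detection of the transition ("tipping")
stage in staged, replicated transcriptome experiments — with the
preprocessing, network-overlay and enrichment analyses that surround it.

## The problem and who this is for

Developmental transitions — the motivating case is the commitment of
cassava fibrous roots to storage-root identity — are often abrupt, and the
stage *just before* the switch leaves a characteristic statistical
signature: a small group of genes whose expression becomes highly variable
across biological replicates, tightly correlated within the group, and
decoupled from the rest of the transcriptome. `dnbtip` is for researchers
with a staged, replicated expression matrix (microarray or RNA-seq) who
want to locate that tipping stage and extract the gene group that marks
it, then relate the group to differentially expressed genes (DEGs) on a
transcription-factor network and to functional gene sets.

## The statistic

For each candidate gene cluster at a stage, using only that stage's
replicate columns:

    CI = SD_in × |PCC_in| / |PCC_out|

* `SD_in` — mean replicate standard deviation of the cluster's genes,
* `|PCC_in|` — mean absolute Pearson correlation over member pairs,
* `|PCC_out|` — mean absolute correlation between members and
  non-members.

Candidates at each stage are genes with a significant change in
replicate-level variability versus the reference stage (per-stage BH-FDR
ceilings, defaults 0.72/0.20/0.25) and a replicate-SD fold-change
`FC_SD ≥ 2`; candidates are clustered by average linkage on `1 − |r|` and
cut at `K = 80`. The stage whose best cluster maximizes CI is the tipping
stage; that cluster is the DNB gene set.

## Worked example

The built-in generator plants a DNB module (60 genes, replicate SD
inflated 3×, pairwise correlation 0.8) at the FR8 stage of a 4-stage ×
3-replicate experiment of 4 000 genes, plus 200 DEG-like genes:

```r
library(dnbtip)

sim <- simulate_experiment(simulation_spec(seed = 1))
res <- dnb_analysis(sim$expr)
res
#> <dnb_result>
#>   tipping stage: FR8
#>   DNB genes: 9
#>   CI trajectory: FR8=1.38

tidy(res)
#> # A tibble: 1 × 8
#>   stage cluster n_genes sd_in pcc_in_abs pcc_out_abs    ci ci_infinite
#>   <chr>   <int>   <int> <dbl>      <dbl>       <dbl> <dbl> <lgl>
#> 1 FR8        34       9 0.881      1.000       0.640  1.38 FALSE

recovery_metrics(res, sim$truth)
#> # A tibble: 1 × 5
#>   stage_correct jaccard precision recall n_recovered
#>   <lgl>           <dbl>     <dbl>  <dbl>       <int>
#> 1 TRUE           0.0615     0.444 0.0667           9
```

Reading this: the planted transition stage (FR8) is identified — only FR8
shows any representative cluster, with composite index 1.38 — and the
winning 9-gene cluster is a fragment of the planted module (precision
0.44 here; at triplicate resolution the stage call is robust while the
module's exact extent is noisy, see the methods vignette). The DNB/DEG
signature contrast used in the network overlay:

```r
sig <- signature_ratios(sim$expr, "FR8", "FR4")
median(sig$sd_ratio_pct[sig$gene_id %in% sim$truth$dnb_genes])
#> [1] 79.1625    # planted DNB genes sit high on the SD-ratio axis

overlap_odds_ratio(paste0("g", 1:10), paste0("g", c(1:5, 11:25)),
                   paste0("g", 1:100))
#> # A tibble: 1 × 7
#>   odds_ratio p_value     a     b     c     d haldane_corrected
#>        <dbl>   <dbl> <int> <int> <int> <int> <lgl>
#> 1          5  0.0255     5     5    15    75 FALSE
```

A full file-driven run (`run_pipeline()`, or `exec/dnb run --config
cfg.yaml`) chains probe collapsing, GeTMM normalization and
low-expression filtering, candidate selection, clustering, CI scoring,
the network overlay (SIF/GraphML/TSV export) and odds-ratio/GO
enrichment, and writes a JSON manifest from which any run can be
reproduced byte for byte.

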