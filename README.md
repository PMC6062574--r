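# umisense

Benchmarking toolkit for UMI-based single-cell RNA-seq protocols, built
around a molecule-level synthetic data generator.

Plate-based scRNA-seq protocols differ enormously in sensitivity (how few
input mRNA molecules they detect), amplification evenness (how many reads a
UMI costs), library cleanliness (doublets, broken cells, cross-cell
contamination) and, downstream, in how many cells a differential-expression
study needs. umisense implements the computational analyses used to make
those comparisons, for method developers and benchmarkers who want them as
reusable, tested functions rather than one-off scripts:

* **Spike-in sensitivity** — per cell, a binomial logistic regression of
  spike-in detection (detected = ≥ 1 UMI) on log10(input molecules);
  inverting the fit at 50% gives the detection limit
  m50 = 10^(−b0/b1), the number of molecules needed for even odds of
  detection. The analytic oracle for the binomial capture model is
  `closed_form_limit(p) = ln(0.5)/ln(1−p)`.
* **mRNA content** — spike-in detection efficiency (observed spike UMIs /
  known spiked molecules) divides the endogenous UMI total to estimate
  molecules per cell.
* **Cell QC** — doublet flagging at multiples of the modal UMI total (KDE
  mode × 1.5), low-quality flagging from nearest-neighbor Spearman
  correlations (median − 3·MAD), fixed read/mapping-rate/UMI/gene
  thresholds, and species-mixing (barnyard) crosstalk quantification with a
  Welch test between protocol variants.
* **Depth & saturation** — exact hypergeometric downsampling of molecule
  tables to fixed read totals, nested across depths so saturation curves
  are monotone; reads-per-UMI evenness statistics.
* **Power simulation** — per-gene NB(μ, φ) moment estimation
  (var = μ + φμ²) from counts, planted log2 fold-changes N(0, 1.5²) on 10%
  of genes, two-group simulation at 24–384 cells per group, Wilcoxon
  rank-sum testing with Benjamini–Hochberg adjustment, TPR/FDR summaries.
* **Synthetic data** — NB expression, binomial capture, Beta-distributed
  per-molecule PCR efficiency with multinomial read allocation, ERCC-like
  spike-in ladders, doublet merging and barcode crosstalk, all with
  ground-truth records for parameter-recovery testing.

## Worked example

```r
library(umisense)

cfg <- sim_config(n_cells = 96, gene_means = rep(20, 1000),
                  gene_dispersions = rep(0.3, 1000),
                  capture_efficiency = 0.2, reads_per_cell = 20000,
                  doublet_rate = 0.05, seed = 42)
design <- spikein_ladder()          # 92 species, 23 levels, 0.12..10,000
ex <- simulate_experiment(cfg, design)

fits <- fit_detection_models(ex$umi, design)
protocol_sensitivity(fits, "demo")
#>     group median_m50 n_cells n_excluded
#> 1:   demo   5.689073      91          1

estimate_mrna_content(ex$umi, design)$median
#> [1] 20086

dbl <- flag_doublets_by_umi(colSums(ex$umi))
sum(dbl)                            # 4 flagged; truth planted exactly 4
#> [1] 4

saturation_curve(ex$table, c(2000, 10000, 20000), seed = 1)[cell == "BC00001"]
#>       cell depth reads_kept umis_detected genes_detected umis_per_read
#> 1: BC00001  2000       2000          1884            309       0.94200
#> 2: BC00001 10000      10000          7495            704       0.74950
#> 3: BC00001 20000      20000         11877            841       0.59385
```

Reading the numbers: at capture efficiency 0.2 and 20,000 reads per cell,
the median cell needs ~5.7 spiked molecules for 50% detection — above the
capture-only limit `closed_form_limit(0.2) = 3.11`, because finite
sequencing depth adds dropout on top of capture. The mRNA-content estimate
(~20,000 molecules) recovers the simulated truth (1,000 genes × mean 20).
All four merged doublet barcodes are flagged at 1.5× the modal UMI total.
The saturation rows show UMIs per read falling from 0.94 to 0.59 as the
library saturates.

A full pipeline run (simulate → QC → saturation → sensitivity → power) with
every artifact and a checksummed manifest:

```r
run_pipeline(read_run_config(), outdir = "demo_run")
```

or from the shell: `Rscript inst/cli/umisense.R run --seed 1 --outdir demo_run`
(subcommands: `simulate`, `qc`, `depth`, `ercc`, `power`, `run`).

## Documentation

`vignettes/umisense-methods.Rmd` describes the generative model and its
assumptions, the detection-limit estimator and its known systematic bias
against the closed-form oracle, the QC rules' exact boundary semantics, and
every design decision taken where the underlying procedure was ambiguous.
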