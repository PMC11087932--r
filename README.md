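# gliomacnv

Tumor-fraction-aware copy-number profiling and glioma CNV-marker
classification from low-pass long-read whole-genome sequencing.

## The problem

The 2021 WHO classification of CNS tumors (CNS5) makes a handful of
copy-number markers decisive for diffuse gliomas:

| marker | meaning |
|---|---|
| complete 1p/19q codeletion | oligodendroglioma |
| no codeletion, IDH-mutant, CNV evidence | astrocytoma |
| +7/−10 signature or *EGFR* amplification (IDH-wildtype) | molecular glioblastoma |
| *CDKN2A/B* **homozygous** (not hemizygous) deletion | WHO grade 4 support |

Low-pass nanopore sequencing makes the raw data cheap, but turning binned
read counts into those calls requires GC/mappability correction,
centromere exclusion, and — crucially — explicit modeling of tumor purity:
at tumor fraction *t* every deviation is attenuated toward diploid, and a
homozygous deletion in an impure sample is numerically identical to a
hemizygous deletion in a purer one. `gliomacnv` implements the complete
chain: reads (BAM/SAM) or fixed-step WIG counts in 500-kb windows →
bias correction → optional panel-of-normals → HMM segmentation with
emission centers `log2((t·c + 2(1−t))/2)` and tumor fraction estimated by
likelihood maximization over a grid → an artificial-admixture regression
(`copy(t) ≈ 2 − 2t`) that types CDKN2A/B deletions as homozygous vs
hemizygous → per-marker calls → a deterministic WHO-style rule engine → a
single self-contained HTML report with a genome-wide plot.

A seeded simulator (negative-binomial counts, smooth GC bias, planted
events at known tumor fraction) makes every stage testable without any
external data. Packages are tidyverse-shaped: profiles are tibbles,
results have `tidy()`/`glance()`/`autoplot()` methods, everything pipes.

## Worked example

Simulate a glioblastoma-like genome (+7, −10, *EGFR* at 8 copies) at
tumor fraction 0.6 and run the in-memory pipeline:

```r
library(gliomacnv)

build   <- genome_build("hg38")
grid    <- bin_grid(build, 5e5)
spec    <- scenario_library(tumor_fraction = 0.6, seed = 11,
                            build = build)[["gbm-like"]]
sim     <- simulate_bin_counts(spec, grid = grid)
profile <- correct_bias(sim$counts, mask = exclusion_mask(grid))
seg     <- estimate_tumor_fraction(profile)
seg
#> <cnv_segmentation> sim_seed11
#>   tumor fraction: 0.6
#>   log likelihood: -2929.264 | emission sd: 0.0954
#>   segments: 26 over 5944 valid bins
```

The estimated tumor fraction (0.6) matches the simulated truth; the
emission noise (~0.095 in log2 units) reflects the preset depth. Marker
calls and classification:

```r
markers <- call_markers(seg)
markers[, c("marker_id", "status", "mean_copy", "fraction_of_bins_altered")]
#> # A tibble: 6 x 4
#>   marker_id status          mean_copy fraction_of_bins_altered
#> 1 CDKN2AB   neutral              1.95                        0
#> 2 EGFR      amplification        6.49                        1
#> 3 ARM_1P    neutral              1.99                        0
#> 4 ARM_19Q   neutral              2.02                        0
#> 5 CHR7      gain                 2.60                        1
#> 6 CHR10     hemizygous_loss      1.41                        1

classify_glioma(markers)
#> <glioma_classification>
#>   CNV-consistent-with: glioblastoma_molecular
#>   grade hint: no_grade4_cnv_evidence
#>   - R3_plus7_minus10_egfr_gbm :: +7/-10 signature and EGFR amplification; IDH unknown (takes precedence over astrocytoma rule)
```

`mean_copy` is the tumor-fraction-attenuated copy value
`2·2^log2ratio` (chr7 at 2.60 ≈ 3 copies at *t* = 0.6); the planted
+7/−10/EGFR genotype is recovered and the rule engine cites the rule it
fired. `autoplot(seg, markers)` draws the genome-wide profile with the
altered markers highlighted.

The file-based pipeline runs from a config and writes every export
(`report.html`, `plot.svg/png`, `markers.tsv/json`, `segments.seg/bed`,
`classification.json`):

```r
cfg <- run_config(input = "sample.bam", build = "hg38",
                  out_dir = "results/sample1",
                  context_path = "context.yaml")  # optional IDH status etc.
run_pipeline(cfg)
```

or from a shell via the thin CLI at `inst/cli/gliomacnv`
(`run`, `simulate`, `fit-baseline`, `version` subcommands). Alignment
itself is out of scope: align nanopore FASTQ with
`minimap2 -ax map-ont --secondary=no ref.fa reads.fq | samtools sort`
and index before passing the BAM.

## Scope

Hg19 and hg38 only (chr1–22, X, Y); no CRAM, no duplicate marking, no
ploidy search, no subclonal modeling. The packaged CDKN2A/B deletion
baseline is synthetic (fitted on a noiseless simulated admixture series,
regenerable with `simulate_admixture_series()` + `fit_baseline()`); refit
it from real normal/tumor data for clinical-grade use. Classification
output is decision support, never a diagnosis.
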