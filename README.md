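# clonesweep

Clonal architecture and selective-sweep dynamics from bulk tumor sequencing.

Bulk sequencing of a tumor reports, per mutated locus, how many reads carry
the variant allele. `clonesweep` converts those allele fractions into
statements about the tumor's clonal structure and the selection acting on a
driver-bearing subclone:

* **Cancer cell fraction (CCF).** The fraction of cancer cells carrying a
  variant, from the VAF, sample purity *p*, and local copy number CN:

  CCF = VAF · (2 + (CN − 2) · CCF_CNV) / p

  with multiplicity-aware correction for gained loci, a strict clonality
  call at CCF > 0.95, the purity-only corrected VAF
  (cVAF = min(VAF/p, 1)), and the mutation-versus-copy-gain ordering call
  (cVAF > 0.5 on a gained locus implies the mutation preceded a gain of
  the variant allele).
* **Sweep dynamics.** Logistic subclone competition
  x(t) = e^{st}/(e^t + e^{st}); adaptive-mutation growth after
  establishment, n(t) = e^{st}/(e^{st} + 2Ns); and hitch-hiking passenger
  frequencies n_i(t) = e^{−μt} (μ/(is))^{1−μ/s}. A per-tumor selection
  coefficient is fitted from the observed subclonal frequency spectrum by
  grid search with a censored binomial read-count likelihood.
* **Architecture metrics.** Shannon diversity H = −Σ p_i ln p_i of the
  10-bin CCF histogram, median CCF, and linearity/branching indices over
  clone trees (fractions of cross-clone mutation pairs in
  ancestor–descendant versus incomparable lineage relations).
* **Expression signatures.** Up/down gene signatures built from the most
  variable genes, pruned for compactness, scored per sample as
  (mean up − mean down)/SD, and associated with binary genomic features
  through a mutual-information-based information coefficient with a
  permutation test.
* **Synthetic data.** A generator for tumors, cohorts, clone trees and
  expression matrices with known truth, so every stage runs and is tested
  without external data.

Coordinates are 1-based with closed intervals (MAF/SEG conventions), allele
fractions are strandless, readers accept gzip transparently, and mutations
outside all segments are analyzed as diploid and flagged.

## Worked example

Simulate a small cohort — three hard-swept tumors whose driver sits on a
gained locus at multiplicity 3, three neutral tumors — and summarize each
tumor's architecture:

```r
library(clonesweep)

cohort <- simulate_cohort(
  c(HARD = 3, NEUTRAL = 3), seed = 7,
  config_overrides = list(HARD = list(driver_multiplicity = 3,
                                      local_cn_at_driver = 4)))

metrics <- dplyr::bind_rows(lapply(cohort, function(t) {
  tab <- compute_ccf_table(t$sample)
  m <- architecture_metrics(tab)
  m$driver_cvaf <- tab$cvaf[tab$gene == "BRAF"]
  m$order_call  <- tab$order_call[tab$gene == "BRAF"]
  m$regime      <- t$truth$regime
  m
}))
print(as.data.frame(metrics), digits = 3)
#>   sample_id n_mutations median_ccf diversity_h n_clonal driver_cvaf
#> 1     S0001          26      0.985       0.586       16       0.803
#> 2     S0002          26      0.972       0.540       14       0.843
#> 3     S0003          26      0.996       0.358       18       0.784
#> 4     S0004         176      0.147       1.558       15       0.485
#> 5     S0005         176      0.168       1.640       20       0.549
#> 6     S0006         176      0.159       1.713       19       0.462
#>                            order_call  regime
#> 1 MUTATION_BEFORE_GAIN_VARIANT_ALLELE    HARD
#> 2 MUTATION_BEFORE_GAIN_VARIANT_ALLELE    HARD
#> 3 MUTATION_BEFORE_GAIN_VARIANT_ALLELE    HARD
#> 4                       INDETERMINATE NEUTRAL
#> 5                       INDETERMINATE NEUTRAL
#> 6                       INDETERMINATE NEUTRAL
```

The hard-swept tumors show the expected signature: the detectable mutation
spectrum collapses onto the clonal cluster (median CCF ≈ 0.98, diversity
H ≈ 0.5 versus ≈ 1.6 for neutral tumors), and the driver's cVAF exceeds
0.5 on its 4-copy locus, calling the mutation-before-variant-allele-gain
order. A deterministic sweep spectrum shows why hard sweeps shed few
hitch-hikers:

```r
simulate_sweep_spectrum(sweep_params(s = 2, mu = 0.001), n_passengers = 3)
#> <sweep_spectrum> s = 2, mu = 0.001, N = 1e+06: driver 0.9900 at
#>   t = 9.90 generations; 3 hitch-hikers (n_1 = 0.000497)
```

File-based runs use the pipeline stages `run_simulate()`, `run_ccf()`,
`run_sweep_fit()` and `run_signature()` (each writes TSV outputs plus a
JSON manifest with the package version, seed and parameters), or the thin
CLI at `inst/scripts/clonesweep.R` with subcommands `simulate`, `ccf`,
`sweep-fit` and `signature`.

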