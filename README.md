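# dippanel

Forensic evaluation of biallelic deletion/insertion polymorphism (DIP)
panels in R.

DIPs are short indel markers typed by capillary electrophoresis: they have
no stutter, short amplicons and low mutation rates, which makes them
attractive for individual identification, kinship testing and
biogeographic-ancestry screening on degraded casework samples. A
laboratory that assembles a DIP multiplex needs to answer three questions
about it: *how well does the panel distinguish two random individuals*,
*how well does it separate true relatives from unrelated pairs*, and *how
much continental-ancestry information does it carry*. `dippanel`
implements the complete statistical tool chain for those questions on
panels of biallelic loci, plus seeded synthetic-data generators so every
analysis can be exercised and calibrated end to end without access to
confidential genotype data.

## What it computes

**Per-locus forensic parameters** (`locus_stats()`), for deletion
frequency *p*, *q* = 1 − *p*, *n* diploid individuals and observed
heterozygosity *Ho*:

- polymorphism information content `PIC = 1 − (p² + q²) − 2p²q²`
- unbiased expected heterozygosity `He = 2pq · 2n/(2n − 1)`
- matching probability `PM = Σ genotype-proportion²`, power of
  discrimination `PD = 1 − PM`
- power of exclusion `PE = Ho²(1 − 2Ho(1 − Ho)²)`, typical paternity
  index `TPI = 1/(2(1 − Ho))`
- Hardy–Weinberg exact test (heterozygote-count enumeration conditional
  on allele counts) and an EM + permutation likelihood-ratio test of
  pairwise linkage disequilibrium, both with Bonferroni thresholds.

**Panel combinations** (`combine_panel()`): `CPM = Π PM`,
`TDP = 1 − Π(1 − PD)`, `CPE = 1 − Π(1 − PE)`, accumulated in log space so
a 43-locus CPM of order 10⁻¹⁶–10⁻¹⁸ is exact and printable as `4.32440E-17`
style strings.

**Kinship likelihood ratios** (`kinship_lr()`, `run_lr_study()`): the
joint probability of a genotype pair under an IBD hypothesis
(*k₀*, *k₁*, *k₂*) is `P(g₁)·[k₀P(g₂) + k₁T(g₂|g₁) + k₂𝟙(g₁=g₂)]`;
multi-locus LRs are products over unlinked loci. `run_lr_study()`
simulates related and unrelated pairs and tabulates accuracy and
false-positive rate at LR limits 1–10⁴, the standard full-/half-sibling
discrimination study.

**Population genetics** (`pairwise_fst()`, `nei_distance()`,
`informativeness_for_assignment()`, `neighbor_joining()`,
`classical_mds()`, `pca_panel()`): Weir–Cockerham θ, Nei's standard
distance *Ds*, Rosenberg's informativeness for assignment *Iₙ*, NJ trees
(Newick out), Torgerson MDS and centered PCA.

**Ancestry assignment** (`stratified_split()`,
`train_frequency_classifier()`, `evaluate_assignments()`): a 75/25
stratified evaluation protocol around a transparent per-class
allele-frequency likelihood classifier, scored by confusion matrix,
accuracy and exact Clopper–Pearson 95% CI.

**Synthetic data** (`sample_frequency_spectrum()`,
`simulate_population()`, `simulate_structured_populations()`,
`simulate_kin_pairs()`): truncated-normal frequency spectra, HWE
genotypes, Balding–Nichols continental structure at tunable F_ST, and
related pairs by direct IBD-state sampling. All generators are
bit-reproducible under a fixed seed.

Everything is tibble-in / tibble-out and pipe-friendly; study objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

A full synthetic evaluation of a 43-locus panel:

```r
library(dippanel)

panel <- sample_frequency_spectrum(n_loci = 43, seed = 2024)
geno <- simulate_structured_populations(
  panel, fst = 0.15,
  sizes = c(africa = 150, east_asia = 150, other = 150),
  continents = c("Africa", "East Asia", "Other"), seed = 2025
)

locus_stats(geno) |> combine_panel()
#> # A tibble: 3 × 6
#>   population     k      cpm cpm_str       tdp   cpe
#>   <chr>      <int>    <dbl> <chr>       <dbl> <dbl>
#> 1 africa        43 2.52e-16 2.51623E-16     1 0.998
#> 2 east_asia     43 4.32e-17 4.32440E-17     1 0.998
#> 3 other         43 2.91e-16 2.91039E-16     1 0.998
```

The CPM column says two random individuals match across all 43 loci with
probability about 10⁻¹⁶: the panel is effectively individualizing, and
the combined exclusion probability (CPE ≈ 0.998) supports trio paternity
work.

```r
study <- run_lr_study(panel, n_pairs = 1000, seed = 2026)
tidy(study)
#> # A tibble: 10 × 4
#>    relationship threshold accuracy false_positive
#>    <chr>            <dbl>    <dbl>          <dbl>
#>  1 full_sibling         1     96.5            3
#>  2 full_sibling        10     87.5            0.2
#>  3 full_sibling       100     68.9            0
#>  4 full_sibling      1000     40.4            0
#>  5 full_sibling     10000     18              0
#>  6 half_sibling         1     80.2           21.5
#>  7 half_sibling        10     29.3            1.5
#>  8 half_sibling       100      1.8            0.1
#>  9 half_sibling      1000      0              0
#> 10 half_sibling     10000      0              0
```

At the conventional LR > 1 limit the panel identifies 96.5% of true full
siblings with a 3% false-positive rate; half siblings are separable only
to a limited extent (80.2% at LR > 1), which is the expected behavior of
a ~40-locus biallelic panel. `autoplot(study)` draws the log₁₀ LR density
curves behind these rates.

```r
split <- stratified_split(geno, 0.75, seed = 2027)
model <- train_frequency_classifier(split$train)
pred  <- predict(model, split$test)
evaluate_assignments(split$test$continent, pred$predicted,
                     labels = model$classes)
#> <dip_ancestry_eval> n = 114, accuracy = 1.0000, 95% CI (0.9682, 1.0000)
#>            truth
#> prediction  Africa East Asia Other
#>   Africa        38         0     0
#>   East Asia      0        38     0
#>   Other         0          0    38
```

(Synthetic classes at F_ST = 0.15 are cleanly separable; real continental
reference panels contain admixed populations and score lower.)

`run_pipeline(default_config(seed = 1), "out/")` runs all of the above as
one config-driven, fully seeded job and writes CSV/TSV/Newick/JSON
artifacts plus a run report.

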