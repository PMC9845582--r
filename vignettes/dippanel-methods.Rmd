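---
title: "Methods: forensic evaluation of biallelic DIP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic evaluation of biallelic DIP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dippanel)
```

This vignette records the statistical models behind `dippanel`, the
conventions the package fixed where several defensible choices existed,
and what its synthetic-data calibration does and does not establish about
real casework data.

## The data model

A *panel* is a set of unlinked autosomal biallelic deletion/insertion
loci. A genotype table is a tibble with `sample_id`, `population`,
optionally `continent`, and one column per locus holding `DD`, `DI`,
`II` or `NA`. Heterozygotes have one canonical spelling (`DI`); the
reader normalizes `ID` on input. Missing genotypes are excluded
locus-wise from every statistic (complete-case per locus) — the standard
convention in forensic frequency work, and the one this package flags
explicitly whenever cells are dropped rather than silently zeroed. A sex
locus such as Amelogenin is metadata by construction: it is simply not a
column of the genotype table, so all panel statistics run on the
autosomal loci only.

## Single-locus parameters

With deletion frequency $p$, $q = 1-p$, $n$ diploid individuals and
observed heterozygosity $H_o$:

$$\mathrm{PIC} = 1 - (p^2+q^2) - 2p^2q^2, \qquad
  H_e = 2pq\,\frac{2n}{2n-1},$$
$$\mathrm{PM} = \sum_g \hat f_g^{\,2}, \quad \mathrm{PD} = 1-\mathrm{PM},
  \qquad \mathrm{PE} = H_o^2\,(1-2H_o(1-H_o)^2), \qquad
  \mathrm{TPI} = \frac{1}{2(1-H_o)}.$$

Three conventions required a decision, because published tables rarely
state them:

- **$H_e$ carries the unbiased $2n/(2n-1)$ correction.** The plain
  $2pq$ variant differs in the fourth decimal at $n \approx 200$; the
  corrected form is what standard forensic calculators (STRAF-style)
  print, and it is what reproduces reference values such as
  $H_e(p=0.8349, n=209) = 0.2763$.
- **PM uses observed genotype proportions**, not HWE-expected ones.
  Both are defensible; observed is the common forensic-software default
  and is exposed as `match_probability()`, with the expected-proportion
  variant available as `match_probability_expected()`.
- **PE and TPI are functions of observed heterozygosity** (not $H_e$);
  both printed anchor pairs ($H_o = 0.6000 \to$ PE 0.2909, TPI 1.2500;
  $H_o = 0.2919 \to$ PE 0.0603, TPI 0.7061) confirm the convention.

Report tables round half-up to 4 decimals (`round_half_up()`); internal
math is always full precision.

### Hardy–Weinberg exact test

`hwe_exact_test()` conditions on the observed allele counts and
enumerates every heterozygote count of matching parity, with

$$P(h \mid n_D, n_I) \propto \frac{n!}{n_{DD}!\,h!\,n_{II}!}\,2^h ,$$

summing the probabilities not exceeding that of the observed
configuration (two-sided exact formulation). This is deterministic and
exact at any realistic sample size — no Markov-chain approximation is
involved. Monomorphic loci return $p = 1$ with a flag. The test suite
checks the implementation against an independent recurrence-based
construction of the same conditional distribution for every
configuration with up to 30 allele copies. Floating-point ties between
equal-probability tails are absorbed by a relative $10^{-9}$ tolerance
when accumulating the p-value.

### Linkage disequilibrium

No single "the" LD test exists for unphased biallelic genotypes; this
package adopts EM + permutation: the four haplotype frequencies are
estimated by EM (only the double-heterozygote cell is phase-ambiguous;
convergence tolerance $10^{-12}$, cap 1000 iterations, convergence
flagged in the output), the statistic is
$\Lambda = 2(\ln L_\text{full} - \ln L_\text{indep})$, and the p-value
comes from permuting one locus's genotype column:
$p = (\#\{\Lambda_\text{perm} \ge \Lambda\} + 1)/(B+1)$. The default is
$B = 10{,}000$ permutations; routine tests use a few hundred, which is
enough to calibrate the null and to pin the maximal-dependence case at
$p = 1/(B+1)$. Pairwise Bonferroni thresholds use
$2\alpha / (m(m-1))$ — the per-pair share over $m(m-1)/2$ pairs, matching
the arithmetic conventionally printed alongside such scans
($m = 43, \alpha = 0.05 \to 0.0001$).

## Panel combinations

$\mathrm{CPM} = \prod \mathrm{PM}_i$,
$\mathrm{TDP} = 1-\prod(1-\mathrm{PD}_i)$,
$\mathrm{CPE} = 1-\prod(1-\mathrm{PE}_i)$. Accumulation is in log space
(`sum(log(pm))`, `log1p`/`expm1` for the complements): a 43-locus CPM
sits around $10^{-16}$–$10^{-18}$, far from double-precision underflow,
but the log-space path keeps every intermediate exact and lets the
mantissa–exponent report string (e.g. `4.32440E-17`) be derived from the
accumulator rather than from a formatted double.

## Kinship likelihood ratios

A relationship is an IBD triple $(k_0,k_1,k_2)$: full siblings
$(\tfrac14,\tfrac12,\tfrac14)$, half siblings $(\tfrac12,\tfrac12,0)$,
unrelated $(1,0,0)$. Note the half-sibling triple is an equivalence
class — avuncular and grandparent–grandchild pairs share it, so
"half-sibling discrimination" rates apply to all second-degree pairs of
this class. The per-locus joint law is

$$P(g_1,g_2 \mid k) = P(g_1)\left[k_0P(g_2) + k_1T(g_2\mid g_1)
  + k_2\,\mathbf 1(g_1=g_2)\right],$$

with $T$ the one-shared-allele kernel (from `DD`: `DD` w.p. $p$, `DI`
w.p. $q$; from `DI`: `DD` $p/2$, `DI` $1/2$, `II` $q/2$; from `II`:
`II` $q$, `DI` $p$). Multi-locus LRs are products over loci, accumulated
as $\log_{10}$ sums; loci missing in either individual are skipped and
counted. Two analytic identities anchor the implementation and are
enforced by exact enumeration in the tests: the nine-pair joint law sums
to 1 for any hypothesis and frequency, and
$\mathbb E[\mathrm{LR} \mid H_2] = 1$ per locus. The full-sibling law is
additionally checked against an independent gene-dropping enumeration
over parental genotypes.

**No co-ancestry ($\theta$) correction is applied**, in simulation or in
LR computation. Published sibling-simulation studies of this kind do not
state one, the reference rates are reproduced without it, and adding
size-biased corrections is orthogonal to the machinery here; it is the
main modeling extension a casework deployment would want.

`run_lr_study()` defines a positive call as strict $\mathrm{LR} > t$
(ties are negative calls) and reports accuracy
$P(\mathrm{LR} > t \mid \text{related})$ and false-positive rate
$P(\mathrm{LR} > t \mid \text{unrelated})$ in percent at limits
$1, 10, 10^2, 10^3, 10^4$.

## Synthetic-data generators

The generators reproduce the statistical structure the analyses assume,
with defaults fixed at the published description of a 43-locus panel in
an East Asian study group:

- `sample_frequency_spectrum()`: deletion frequencies from a normal with
  mean 0.4993 and SD 0.0954, truncated to the reported range
  [0.3080, 0.6480], drawn by inverse-CDF so no rejection loop disturbs
  reproducibility. A truncated normal was chosen because only
  mean/SD/range are reported; with these near-symmetric bounds its mean
  shifts negligibly from the target.
- `simulate_population()`: HWE genotypes, per-locus deletion dosage
  $\sim \text{Binomial}(2, p)$, loci independent (the panels in question
  pass pairwise LD screens, so no linkage is modeled).
- `simulate_structured_populations()`: Balding–Nichols — subpopulation
  frequency $\sim \text{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, then HWE. Under
  this model the Weir–Cockerham estimator recovers $F$, which the tests
  verify at $F = 0.10$ with 500 + 500 individuals and 43 loci.
- `simulate_kin_pairs()`: related pairs by direct IBD-state sampling
  rather than explicit parental gene-dropping; for unlinked autosomal
  loci the two constructions are distributionally identical, and the
  IBD form is verifiable against exact enumeration (the tests do both,
  plus an exact-convolution check of the full multi-locus
  $\log_{10}\mathrm{LR}$ distribution).

**What passing tests show, and what they do not.** The generators
contain no genotyping error, null alleles, mutation, linkage, admixture
or co-ancestry. Calibration successes on this synthetic family therefore
establish the correctness of the estimators and the internal consistency
of the simulation design — not the field performance of a physical panel
on real populations, where those unmodeled features exist. The ancestry
benchmark illustrates this sharply: three Balding–Nichols classes at
$F_{ST} = 0.15$ are almost perfectly separable by the frequency
classifier, whereas real continental panels with admixed reference
populations score around 0.8.

## Population-genetics conventions

- **$F_{ST}$** is Weir–Cockerham $\theta$ (the default of the standard
  population-genetics software this estimator is associated with),
  multi-locus as the ratio of summed variance components. Negative
  estimates are retained in the reported matrix; a zero-clamped copy
  feeds distance-based methods (`clamp = TRUE`).
- **Nei's distance** is the standard $D_s$ with gene identities pooled
  across loci before the log-ratio (the PHYLIP `gendist` convention).
- **$I_n$** uses natural log by default, with a `base` argument since
  the measure is sometimes tabulated in bits; $I_n$ values are clamped
  at zero against $10^{-16}$-scale round-off, which is harmless because
  $I_n = 0$ exactly iff all populations share identical frequencies.
- **Neighbor joining** delegates the Saitou–Nei agglomeration to
  `ape::nj()` and then applies the common negative-branch adjustment
  (negative length zeroed, its magnitude transferred to the adjacent
  edges so leaf-to-leaf path lengths are preserved); the number of
  adjusted branches is recorded on the result. On additive matrices no
  adjustment triggers and recovery is exact, which the tests enforce on
  random trees of up to 8 taxa.
- **MDS** is Torgerson double-centering via `stats::cmdscale`, with a
  deterministic sign convention (largest-magnitude loading positive per
  axis). **PCA** (`stats::prcomp`) centers but does not scale — dosages
  and frequencies are already on a common scale, and scaling would
  up-weight near-monomorphic loci; constant columns are dropped,
  missing dosages mean-imputed per locus.

## Ancestry evaluation protocol

Stratified 75/25 split per class, seeded; the reference classifier is
the per-class allele-frequency likelihood model (pseudocount 0.5 per
allele, so learned frequencies are strictly interior and no class
assigns zero likelihood), scoring by summed log HWE genotype
probabilities with a uniform prior, argmax assignment with deterministic
ties by label order. The paper-grade evaluation surface — the confusion
matrix, trace/total accuracy and *exact* (Clopper–Pearson) binomial CI —
is classifier-agnostic: externally trained predictions (gradient
boosting, SVM, random forest, ...) can be passed straight to
`evaluate_assignments()`. Clopper–Pearson was fixed because it is the
interval that reproduces published accuracy CIs from published
confusion counts, e.g. 800/971 correct $\to$ 0.8239 (0.7984, 0.8474).

## Problem sizes

The shipped test-suite and acceptance-script scales are chosen so a full
run stays interactive on one CPU: the kinship reference simulation uses
10 replicates × 1000 pairs per class × 43 loci (≈ 2 s), the LD null
calibration 60 replicates at $B \approx 200$ permutations, the
exhaustive HWE cross-check all configurations with ≤ 30 allele copies,
and the structured-population calibrations 500–1000 individuals. All are
comfortably beyond the sizes at which the estimators' small-sample
behavior stabilizes.

## Known limitations

- Biallelic loci only; no STR/multi-allelic support.
- No mutation, genotyping-error, silent-allele or $\theta$-correction
  models; no linked-marker kinship.
- VCF import is a best-effort convenience for biallelic indel records
  (shorter allele = deletion); the owned TSV dialect is the primary
  format.
- Parent–child/trio paternity LRs are not implemented; PE/TPI cover the
  single-locus parameter side only.
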