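---
title: "Permutation-based multiple-testing correction for cis-QTL scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based multiple-testing correction for cis-QTL scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlperm)
```

## The model

A cis-QTL scan asks, for each molecular phenotype $P$ measured in $N$
samples, which of the $L$ variants within $\pm W$ bp of the phenotype's
anchor is most strongly associated, and how surprising that best association
is. `qtlperm` works on the Pearson-correlation scale: the scan computes
$r_j = \mathrm{cor}(P, g_j)$ for every dosage vector $g_j$ in the window,
keeps the variant maximizing $|r|$, and converts it with
$t = r\sqrt{df/(1-r^2)}$ to the two-sided nominal P-value $p_n$. This is
algebraically the test of $\beta \ne 0$ in $P = \beta g + \epsilon$ fitted
by least squares, which the test suite verifies against `lm()` to $10^{-10}$;
the correlation form is preferred because after standardizing the dosage
matrix once, every rescan of a permuted phenotype is a single
matrix–vector product.

$p_n$ is the minimum over $L$ correlated tests and needs correction. Three
permutation schemes are provided; all shuffle only the phenotype, leaving
the genotype matrix — and hence the LD structure among variants — intact.

**Direct.** After $R$ permutations with $r$ null best associations at least
as strong as the observed one,
$$p_d = \frac{r+1}{R+1},$$
the standard empirical P-value, exactly uniform under the null but bounded
below by $1/(R+1)$.

**Adaptive.** Permutation effort should concentrate on the phenotypes that
matter. The scheme permutes until $B$ exceedances have occurred or $M$
permutations are spent and reports
$$p_a = \frac{\min(r,B)+1}{\min(R,M)+1}.$$
Defaults are $B = 100$, $M = 100{,}000$, giving a floor of
$\approx 10^{-5}$. The stop condition is evaluated per permutation (batch
results are truncated at the permutation where the $B$-th exceedance
lands): checking only between coarse batches overshoots $B$, which deflates
$p_a$ for insignificant phenotypes and visibly breaks null uniformity. Note
the sequential estimator is conservative by a factor of roughly
$(B+1)/B$, which is why a toy stop count such as $B = 10$ should not be
used when calibrated P-values are the goal.

**Beta approximation.** The $k$-th smallest of $n$ independent uniforms is
$\mathrm{Beta}(k, n)$. The per-permutation minimum P-value is therefore
modelled as $U \sim \mathrm{Beta}(k, n)$, but with both shapes free: LD
makes the effective number of tests $n$ smaller than $L$, and $\hat{k}$ near
1 is a diagnostic that the fitted object really is a minimum. Given null
minima $p_1, \dots, p_R$, the shapes maximize
$$\mathcal{L}(k, n) = (k-1)\sum_r \ln p_r + (n-1)\sum_r \ln(1-p_r)
  - R \ln\!\frac{\Gamma(k)\Gamma(n)}{\Gamma(k+n)},$$
and the adjusted P-value is the fitted CDF at the nominal value,
$p_b = P(U \le p_n)$ — the regularized incomplete beta function, defined on
all of $(0,1)$ with no permutation-count floor. This is the core of the
package: the extreme tail of the null is characterized from ordinary-sized
permutation runs instead of being sampled directly.

**Across phenotypes.** Phenotype-level adjusted P-values go through the
Storey–Tibshirani procedure: $\pi_0(\lambda) = \#\{p > \lambda\} / (m(1 -
\lambda))$ on a $\lambda$ grid, smoothed by a cubic spline and read off at
$\lambda_{\max}$; q-values are $\pi_0$-scaled step-down Benjamini–Hochberg
adjustments (with $\pi_0 = 1$ the two coincide exactly, which the tests
assert against `p.adjust`). Because QTL studies expect many true
associations, learning $\pi_0 < 1$ from the data recovers power that BH
leaves on the table; ST calls are always a superset of BH calls at the same
level.

## Numerical choices

* **Beta MLE.** BFGS on $(\log k, \log n)$ — positivity by
  reparameterization — with the analytic digamma gradient,
  method-of-moments starting values, and up to three deterministically
  jittered restarts. The optimizer consumes no RNG, so fits never perturb
  the permutation streams. Inputs are clamped to $[10^{-300}, 1-10^{-16}]$
  before logs. The likelihood normalizer is the beta function
  $\Gamma(k)\Gamma(n)/\Gamma(k+n)$.
* **P-value transform.** $1 - r^2$ is floored at $10^{-16}$ and P-values at
  the smallest positive double, so a perfect correlation never produces a
  zero. `beta_adjusted_p(..., log.p = TRUE)` serves results far below
  double underflow; the linear path is exact down to at least $10^{-200}$.
* **Tie handling.** Exceedance counting is on the P-value scale with ties
  counted as exceedances (conservative). Equally strong correlations
  resolve to the lowest variant index, i.e. the lowest genomic position —
  deterministic across runs.
* **Ranks.** The inverse normal transform uses offset $\mathrm{rank}/(n+1)$
  with average ranks for ties, then rescales to mean 0, sd 1; a seeded
  random tie-break is available.
* **Degrees of freedom.** With $C$ covariates residualized out of both
  sides, the default df is $N - 2 - C$; `df_policy = "legacy"` keeps
  $N - 2$ for compatibility with implementations that ignore the lost
  dimensions (and is anticonservative when $C$ is large).
* **Reproducibility.** Every phenotype draws from an RNG substream seeded
  by a stable hash of (run seed, phenotype id). Chunked runs (`--chunk i
  n`, contiguous coordinate-balanced groups, anchors sharing a coordinate
  kept together) therefore concatenate to exactly the whole-run output.

## Coordinates and formats

VCF positions are 1-based; BED intervals 0-based half-open. A phenotype's
cis-window anchor is `start + 1` — the TSS-style convention — and signed
variant distance is `POS − anchor`; the BED `end` is not consulted.
Dosages come from the `DS` FORMAT field when present (they are "dosages"
first), else from `GT` allele counts; missing genotypes default to
per-variant mean imputation (preserving $N$), with a drop-sample policy
available. Region queries on bgzipped files require a Tabix index and are
delegated to Rsamtools; plain-text files are accepted for whole-file runs.
No MAF filter is applied unless requested (`maf_min = 0`); zero-variance
variants are always removed since their correlation is undefined.

## What the generator emulates — and what it does not

`simulate_genotypes()` draws two latent Gaussian AR(1) haplotype processes
along the variant index and thresholds them at the MAF-implied quantiles,
giving Hardy–Weinberg 0/1/2 dosages whose adjacent-variant correlation
rises with `ld_rho`; `simulate_phenotypes()` adds planted
`slope × dosage` effects, optional covariate structure and Gaussian noise.
This reproduces the features the method's correctness actually depends on —
a variable-MAF spectrum, exchangeable samples under the null, LD redundancy
compressing the effective test count — and the tests confirm the expected
signatures (e.g. median $\hat{n} < L$ at `ld_rho = 0.9`, $\hat{n} \approx
L$ at 0). It does **not** emulate realistic LD block structure,
allele-frequency skew, phenotype heavy tails (unless you disable
normalization), population stratification, or missingness patterns of real
cohorts; passing tests show the statistics behave as designed under their
stated assumptions, not that any particular real dataset meets them.

Default study conditions used by the property suite: the calibration
fixture uses 200 phenotypes, $N = 150$, $L = 50$, $R = 200$ (and the
adaptive scheme at its typical $B = 100$); the concordance fixture compares
beta fits from 1000 permutations against direct estimates from 10,000 on 60
phenotypes with effect slopes from 0 to 0.5 under moderate LD; the beta
shape recovery battery uses 200 phenotypes × 1000 minima of $L = 100$
uniforms. These sizes keep the full suite under a minute while leaving the
Monte-Carlo error of each assertion well inside its tolerance.

## Known limitations

* One chromosome per fit: `qtl_map()` derives a single genotype slab from
  the selected phenotypes' span. Genome-wide, multi-chromosome runs are the
  chunk loop's job (one chunk never spans chromosomes).
* The beta approximation extrapolates: a fit from 1000 permutations can be
  evaluated at $10^{-20}$, and its validity there rests on the beta model of
  the tail (supported by the goodness-of-fit behaviour, not proof).
* $\pi_0$ estimation is unstable below ~100 phenotypes (a warning is
  issued; a fixed-$\lambda$ fallback exists).
* Only biallelic dosage semantics: no phased haplotypes, multi-allelic
  decomposition, structural variants, or BCF.

```{r example, eval = FALSE}
# A minimal end-to-end run on generated data
cfg <- sim_config(n_samples = 150, n_variants = 80, n_phenotypes = 20,
                  effects = data.frame(phenotype = 1, variant = 40, slope = 1),
                  ld_rho = 0.5, seed = 1)
g <- simulate_genotypes(cfg)
sim <- simulate_phenotypes(g, cfg)
paths <- write_fixture(g, sim$phenotypes, dir = tempfile(), bgzip = TRUE)
fit <- qtl_map(paths$vcf, paths$bed, permutations = 1000, seed = 1)
summary(fit)
qtl_fdr(fit, fdr = 0.05)
```
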