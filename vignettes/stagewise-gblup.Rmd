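---
title: "Stage-wise pedigree and genomic BLUP for clonal breeding trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise pedigree and genomic BLUP for clonal breeding trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagegs)
```

## The problem

Clonal crops such as cassava are improved through a multi-stage pipeline:
a large clonal evaluation trial (CET) of unreplicated single-row plots,
followed by preliminary, advanced and uniform yield trials (PYT, AYT, UYT)
with replication, more locations, and progressively fewer clones. The
resulting data are severely unbalanced: early-stage clones have one or two
plots, check varieties are replicated everywhere, and each added stage
brings new year x location x block combinations. `stagegs` implements the
mixed-model machinery used to analyse such data with either pedigree or
marker information, and a synthetic trial generator with the same
statistical structure for validating that machinery.

## The model

For one trait, the phenotype vector $y$ is modelled as

$$ y = Xb + Z_1 a + Z_2 a_L + \varepsilon $$

where $b$ contains the mean plus fixed effects of every year x location x
block-within-location combination, $a$ is the vector of additive clone
effects, $a_L$ the genotype-by-location interaction effects, and
$\varepsilon$ the residual. The random effects are

$$ a \sim N(0,\, \sigma^2_a K), \qquad
   a_L \sim N(0,\, \sigma^2_{aL} K_L), \qquad
   \varepsilon \sim N(0,\, \sigma^2_e I), $$

with $K$ either the pedigree relationship matrix $A$ (tabular method:
$A_{ii} = 1 + \tfrac12 A_{sd}$, $A_{ij} = \tfrac12(A_{js} + A_{jd})$,
unknown parents contributing zero) or the VanRaden genomic matrix

$$ G = \frac{M_c M_c'}{\sum_i 2 p_i q_i}, $$

where $M_c$ is the dosage matrix column-centred by $2p_i$ and $p_i$ is the
allele frequency computed from the data after heterozygote imputation. $K_L$
is block-diagonal over locations: for each location, the sub-matrix of $K$
over the clones observed there. Interaction effects are therefore
kinship-correlated within a location and independent across locations, with
a single homogeneous variance $\sigma^2_{aL}$.

Plot-level heritability and the interaction's coefficient of determination
are variance shares:

$$ h^2 = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_{aL} + \sigma^2_e},
   \qquad
   c^2 = \frac{\sigma^2_{aL}}{\sigma^2_a + \sigma^2_{aL} + \sigma^2_e}. $$

Fixed effects use drop-first-level reference coding, so $X$ always has full
column rank; a dataset with a single environment collapses to the intercept
alone. All clones, checks included, are treated as random with the same
kinship; traits are fitted independently.

## Estimation

Solutions come from Henderson's lambda-augmented mixed-model equations with
$\lambda_1 = \sigma^2_e/\sigma^2_a$ on the clone block and
$\lambda_2 = \sigma^2_e/\sigma^2_{aL}$ on the interaction block
(`solve_mme()`). Variance components are estimated by REML (`reml_fit()`)
using average-information (AI) Newton steps computed on the same equations,
with these numerical choices:

* **Step control.** Each iteration tries the full AI step (clamped at the
  lower bound), then halved AI steps, then the EM update, accepting the
  first candidate that does not decrease the restricted likelihood. EM is
  monotone, so the likelihood trajectory is non-decreasing by construction
  (this is asserted in the test suite).
* **Bounds.** Components are bounded below by $10^{-8}\,\mathrm{var}(y)$ so
  the variance ratios stay finite; a component pushed to the bound with a
  negative score stays pinned. A constant response therefore returns all
  components at the bound with a finite likelihood rather than an error.
* **Convergence.** Both $|\Delta \log L| < 10^{-6}$ and a maximum relative
  parameter change below $10^{-5}$, within 200 iterations; non-convergence
  is an error that carries the iteration trajectory.
* **Starting values.** $(0.35, 0.15, 0.5) \cdot \mathrm{var}(y)$ — a
  moderate-heritability split that is well inside the parameter space.
* **Singular $G$.** A VanRaden $G$ built with data allele frequencies always
  carries the ones vector in its null space (column centring makes
  $1'G1 = 0$), and with fewer markers than clones it is rank-deficient more
  broadly. Before inversion, $K$ is blended as $(1-\beta)K + \beta I$ with
  $\beta = 0.01$. The blend is chosen automatically from the Cholesky pivot
  ratio, not from mere factorization success: the theoretical null space can
  round to a tiny positive pivot, and an unblended inverse in that state is
  numerically worthless.
* **Likelihood value.** The restricted log-likelihood is computed from the
  MME factorization via
  $\log|V| + \log|X'V^{-1}X| = (n-p)\log\sigma^2_e + \log|\Gamma| + \log|C|$,
  and is verified in the tests against an independent dense $V$-form
  computation, as are the AI trace identities.

Likelihood-ratio tests (`lrt_compare()`) use
$\mathrm{LRT} = 2(\log L_\mathrm{full} - \log L_\mathrm{restricted})$
against $\chi^2_1$ by default. Because the dropped variance component sits
on the boundary of its parameter space, the 50:50 mixture reference is
available via `boundary = TRUE`, but the plain $\chi^2_1$ is the default to
match standard practice in breeding-trial software. A restricted fit pinned
at the boundary can numerically edge above the full fit, giving a slightly
negative statistic; it is clamped to zero with a warning. The "without
genotype" restricted model keeps the interaction term and is fitted by
promoting the block-diagonal structure to the single random effect
(`fit_no_genotype()`).

## SNP effects, selection index, gains

Marker effects are backsolved from genomic breeding values as
$\hat m = M_c' (M_c M_c')^{+} \hat a$ using a symmetric pseudo-inverse
(`backsolve_snp_effects()`). Because $X$ contains the intercept, the clone
BLUPs sum to zero exactly even with a blended $G$, so $M_c \hat m$
reconstructs $\hat a$ to numerical precision whenever the marker count
reaches the clone count — an identity the suite asserts at $10^{-6}$.

The selection index is the empirical weighted sum
$SI = 10\,\mathrm{FRY} + 10\,\mathrm{DMC} + 10\,\mathrm{DY} +
5\,\mathrm{FSY} + 3\,\mathrm{HI}$ over breeding values in original trait
units; an optional standardized mode exists but is off by default because
the weights imply no standardization. Genetic gain for a selected fraction
is the mean selected breeding-value deviation as a percent of the
phenotypic trait mean; the paper-side alternative of a check-mean baseline
is available by passing that mean instead. Ties in rankings are broken by
clone ID so results are deterministic.

## Cross-validation

`cross_validate()` implements ten-fold clone-level validation: folds
partition clones (never records), variance components are re-estimated on
each training set, and validation clones' predicted genetic values come
from the mixed-model equations with their records deleted — i.e. purely
through kinship. Three design choices deserve a note:

* **Pseudo-phenotypes** (predicted genetic value plus the clone's mean
  residual) are computed once from the full-data fit and held fixed across
  folds. This makes the validation target independent of the fold model;
  computing residual means per training fold is supported by the same
  functions but is not the default.
* **The heritability in the accuracy denominator** is the full-data
  estimate of the same analysis (pedigree $h^2$ for pedigree CV, genomic
  $h^2$ for genomic CV).
* **Calibration of the accuracy formula.** $\mathrm{accuracy} =
  \mathrm{PA}/\sqrt{h^2}$ is exact when each clone contributes one plot:
  then the pseudo-phenotype is a plot-adjusted phenotype whose correlation
  with the true breeding value is $\sqrt{h^2}$. With $r$ replicated plots
  per clone the proper denominator would be the clone-mean heritability
  $\sqrt{r h^2 / (1 + (r-1)h^2)}$-style, and the plot-level formula can
  exceed 1. The package follows the plot-level convention throughout
  (matching common usage); the calibration experiments in the test suite
  therefore use unreplicated single-plot designs, where the formula is the
  estimator of $\mathrm{cor}(\mathrm{GEBV}, \mathrm{true\ BV})$.

## What the simulator emulates — and what it does not

`sim_config()` defaults describe a realistic cassava panel: 290 progeny
from 30 biparental crosses among 20 founder parents (a few founders carried
through all stages as replicated checks), 5 000 unlinked biallelic SNPs
with founder allele frequencies uniform on [0.05, 0.5] and 3.34% missing
calls, and a four-stage plan whose survival fractions prune the test clones
290 → 136 → 72 → 21 while the cumulative location count grows 4 → 5 → 7 →
10 over six years. Per-trait means and variance components are back-derived
from one-stage clonal-trial estimates (heritabilities 0.47–0.73,
interaction ratios 0–0.12, residual CVs 0.04–0.82), e.g. FRY: mean 29.24
t/ha, $(\sigma^2_a, \sigma^2_{aL}, \sigma^2_e) = (123.4, 17.6, 110.8)$
t²/ha².

Structural choices, made once:

* **Unlinked loci.** No genetic map is modelled; each marker segregates
  independently (one random allele per parent). Sufficient for testing
  estimation machinery; useless for LD or map-based questions.
* **Exact additive variance.** Marker effects are drawn i.i.d. normal and
  rescaled so the variance of true breeding values across the simulated
  clones equals $\sigma^2_a$ exactly, which makes recovery targets
  well-defined. Note the consequence: in a family-structured population the
  sample variance of correlated effects understates the $A$-metric
  variance, so exact-variance scaling matches the model's $\sigma^2_a$ only
  when mean relatedness is near zero. Parameter-recovery experiments
  therefore use single-progeny crosses among distinct founder pairs.
* **Interaction truth.** G×L deviations are drawn per location from
  $N(0, \sigma^2_{aL} A)$ — kinship-correlated within a location,
  independent across locations — exactly the covariance the block-diagonal
  model assumes.
* **Environments.** One effect per year-location-block cell,
  $N(0, 0.25\,\sigma^2_e)$ by default; these are nuisance fixed effects in
  the analysis, so their scale is immaterial beyond conditioning.
* **Survival.** Stage survival selects the top clones by a noisy index
  (configurable to random), mimicking selection-driven unbalance.
* **Missingness** is i.i.d. Bernoulli per genotype call; real GBS
  missingness is marker- and clone-structured, so QC behaviour on real data
  will differ in the tails.

Not modelled: linkage maps, dominance and epistasis, read-level genotyping
error, spatial field trends, heterogeneous residual variances across
trials. Passing tests show the estimation machinery is correct under the
stated generative model, not that these phenomena are harmless in real
data.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
pop <- simulate_population(cfg)
records <- simulate_trials(pop)
geno <- impute_missing(
  mask_genotypes(pop$genotypes, cfg$missing_rate, seed = 43)
)
qc <- apply_qc(geno) # call rate 0.90, MAF 1/sqrt(2N)
G <- genomic_G(impute_missing(qc$genotypes))
A <- pedigree_A(pop$pedigree)[rownames(G), rownames(G)]

one_stage <- assemble_stage_dataset(records, 1)
fit_g <- fit_blup(one_stage$records, "FRY", G, kind = "genomic")
glance(fit_g) # variance components, h2, c2, logL
tidy(fit_g) # per-clone GEBVs

cv <- cross_validate(one_stage$records, "FRY", G,
  kind = "genomic", k = 10, seed = 44
)
glance(cv) # mean +/- sd predictive ability, accuracy, bias
```

The whole analysis — QC, both kinships, per-trait and per-stage-depth fits,
likelihood-ratio tests, cross-validation, the selection index and the
one-stage-genomic versus four-stage-pedigree ranking comparison — is driven
by `run_pipeline()`, from an in-memory list or a YAML file.

## Problem sizes in the test suite

The suite exercises the machinery at sizes chosen to make the statistical
assertions sharp while remaining quick to run: oracle-equivalence fixtures
use 8–13 clones so the dense $V$-form inverse is exact and cheap; the
parameter-recovery experiment uses 50 replicates of 300 unrelated clones at
4 locations x 2 reps (2 400 records, a ~1 500-dimensional coefficient
matrix per REML iteration); cross-validation calibration uses a 300-clone,
2 000-marker single-plot clonal trial; gene-dropping agreement uses 50 000
drops on a 20-member pedigree. Larger runs change none of the code paths,
only the constants.

## Known limitations

* Single-trait REML only; the trait correlations reported by the
  comparison machinery are correlations of independently fitted breeding
  values, not multi-trait genetic correlations.
* One homogeneous interaction variance across locations; no
  location-specific or factor-analytic G×E structures.
* Dense linear algebra throughout: comfortable to a few thousand clones
  and coefficient matrices of order ~5 000, not designed for national-scale
  evaluations.
* The accuracy convention is plot-level (see above); with heavily
  replicated clones it overstates accuracy relative to the clone-mean
  formula.
* No single-step (combined pedigree-genomic) matrix, metafounders, or
  sparse A-inverse rules — at a few hundred clones the dense tabular A is
  simpler and exact.
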