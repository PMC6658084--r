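# stagegs

Stage-wise pedigree and genomic BLUP for clonal breeding trials.

Clonal crops such as cassava move through a multi-stage selection pipeline —
an unreplicated clonal evaluation trial (CET), then preliminary, advanced
and uniform yield trials (PYT, AYT, UYT) with replication at more locations
and progressively fewer clones. The resulting records are heavily
unbalanced, and a central practical question is whether genomic prediction
at the *first* stage ranks clones as well as pedigree analysis of the full
four-stage data. `stagegs` is for quantitative geneticists and breeding
analysts who want that analysis as tested, reusable functions rather than a
one-off script.

## The model

For each trait, records are analysed with the mixed model

```
y = X b + Z1 a + Z2 aL + e
a  ~ N(0, sigma2_a  K)         K = A (pedigree) or G (genomic)
aL ~ N(0, sigma2_aL K_L)       K_L = block-diagonal of per-location K blocks
e  ~ N(0, sigma2_e  I)
```

where `b` holds the mean and year x location x block-within-location fixed
effects, `a` the clone breeding values (EBVs under `A`, GEBVs under `G`),
and `aL` genotype-by-location deviations that are kinship-correlated within
a location and independent across locations. `A` comes from the tabular
method with inbreeding propagated (a self-cross gives diagonal 1.5);
`G = Mc Mc' / sum(2 p q)` is the VanRaden matrix from allele-frequency-
centred dosages after call-rate/MAF filtering (MAF threshold `1/sqrt(2N)`)
and heterozygote imputation. Variance components are estimated by
average-information REML on Henderson's mixed-model equations; heritability
is `sigma2_a / (sigma2_a + sigma2_aL + sigma2_e)`. Ten-fold clone-level
cross-validation reports predictive ability (correlation of predicted
genetic values with pseudo-phenotypes), accuracy (`PA / sqrt(h2)`) and bias
(`1 - slope`). SNP effects are backsolved as `m = Mc' (Mc Mc')^+ a`, and an
empirical selection index `10*FRY + 10*DMC + 10*DY + 5*FSY + 3*HI` drives
top-fraction selection, genetic-gain estimates and ranking comparisons.

A synthetic biparental-cross generator (`sim_config()`,
`simulate_population()`, `simulate_trials()`) produces populations and
unbalanced multi-stage trials with this exact statistical structure, so
every estimator in the package can be validated against known truth.

## Worked example

```r
library(stagegs)

cfg <- sim_config(n_markers = 2000, seed = 42) # 290 progeny, 30 crosses
pop <- simulate_population(cfg)
records <- simulate_trials(pop)
geno <- impute_missing(
  mask_genotypes(pop$genotypes, cfg$missing_rate, seed = 43)
)

qc <- apply_qc(geno)
#> Marker QC: 2000 markers in; removed 0 (call rate < 0.9),
#>   42 (MAF < 0.04016); retained 1958.
G <- genomic_G(impute_missing(qc$genotypes))

one <- assemble_stage_dataset(records, 1)
#> 1-stage dataset (CET): 1760 records, 295 clones, 4 locations, 5 years

fit_g <- fit_blup(one$records, "FRY", G, kind = "genomic")
#> Genomic BLUP fit for FRY
#> AI-REML fit (1760 records, 295 clones)
#>   sigma2_a = 101.5, sigma2_aL = 18.3, sigma2_e = 108.8
#>   h2 = 0.444, c2 = 0.080, logL = -6569.578 (7 iterations)

cross_validate(one$records, "FRY", G, kind = "genomic",
               k = 10, seed = 44, full_fit = fit_g)
#> 10-fold clone-level CV, genomic analysis, trait FRY (h2 = 0.444)
#>   pa        0.66 +/- 0.15
#>   accuracy  0.99 +/- 0.23
#>   bias      0.01 +/- 0.30
```

The generator's truth for FRY is `h2 = 0.49` with an interaction share of
0.07; the one-stage genomic fit recovers 0.44 and 0.08 from 1 760
unbalanced records. Predictive ability 0.66 is the fold-mean correlation
between kinship-only predictions of held-out clones and their
pseudo-phenotypes; bias near zero says the regression of pseudo-phenotypes
on predictions has slope near one. (Accuracy uses the plot-level `h2`
denominator, which overstates accuracy when clones have several plots —
see the methods vignette.) `tidy(fit_g)` returns the per-clone GEBVs,
`glance(fit_g)` the variance components, and `run_pipeline()` drives the
whole QC → kinship → fits → LRT → CV → selection-index workflow from one
configuration list or YAML file.

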