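# wolfscan

Analysis toolkit for studies of chronic radiation exposure in wild mammal
populations — built around the grey wolves of the Chornobyl Exclusion Zone,
where a resident population has lived under elevated ¹³⁷Cs/⁹⁰Sr exposure
for roughly seven generations. The package implements four connected
analyses plus a fully seeded synthetic-data generator with ground truth:

1. **Radiological dose reconstruction** — per-animal internal (¹³⁷Cs tissue
   activity; ⁹⁰Sr via a soil-to-tissue concentration ratio) and external
   dose rates (µGy/h), annual (mGy/y) and lifetime (mGy) doses, and Welch
   group comparisons. The model is linear in the measurements:
   internal ¹³⁷Cs rate = A(Bq/kg) × 2.7×10⁻⁴, internal ⁹⁰Sr rate =
   soil(kBq/m²) × 0.86 × 6.38×10⁻⁴, external rate = measured dosimeter
   average or soil × 1.1×10⁻⁴; lifetime dose = rate × 8760/1000 × age.
2. **Genotype QC** — per-call DP > 8 / GQ > 20 masking, biallelic autosomal
   SNP and < 20%-missingness site filters, and windowed LD pruning
   (indep-pairwise 50/10/0.1).
3. **Lineage-specific selection scan** — per-site Weir–Cockerham FST for
   the focal/sister/outgroup pairs, Cavalli–Sforza branch lengths
   T = −ln(1 − F\_ST), the population branch statistic
   PBS = (T_fs + T_fo − T_so)/2, and population branch excess
   PBE = PBS − T_so · med(PBS)/med(T_so), with zero-truncated z-scores,
   BH-adjusted normal-tail p-values, outlier tiers at −log₁₀(p_adj) > 8/15
   and nearest-gene annotation of outliers.
4. **Dose-correlated expression screen and deconvolution** — log₂(CPM+1)
   normalisation, Spearman gene significance with student asymptotic
   p-values, top-0.95-|ρ|-quantile gene selection, module eigengenes with
   nested-model likelihood-ratio tests, pathway PCA, and NNLS leukocyte
   deconvolution against reference profiles.

## Worked example

```r
library(wolfscan)

# dose reconstruction for one collared animal:
# 10,000 Bq/kg internal 137Cs, home-range soil 90Sr 1,000 kBq/m2,
# soil 137Cs 2,000 kBq/m2, age 4
rec <- data.frame(animal_id = "w1", population = "focal", age_years = 4,
                  activity_bqkg_wet = 10000, soil_sr90_kbqm2 = 1000,
                  soil_cs137_kbqm2 = 2000)
dose_rates(rec)[, c("internal_cs137_rate", "internal_sr90_rate",
                    "external_cs137_rate", "total_rate", "lifetime_dose")]
#>   internal_cs137_rate internal_sr90_rate external_cs137_rate total_rate lifetime_dose
#> 1                 2.7            0.54868                0.22    3.46868      121.5425
```

The three component rates are the coefficient products (2.7, 0.549 and
0.22 µGy/h); their 3.47 µGy/h total over four years of 8760-hour exposure
accumulates 121.5 mGy. Annualizing the exposed-cohort mean printed in the
study, `annualize(5.4)` gives 47.304 mGy/y — the "47 mGy/y" figure — about
47× the 1 mSv/y public dose limit.

A full synthetic run (three-population genotypes with 50 planted selected
loci, dose cohorts, an expression matrix with 20 planted dose genes):

```r
cfg  <- sim_config()
gen  <- simulate_three_pop_genotypes(cfg, seed = 1)
gm   <- site_filters(mask_low_quality(gen$genotypes), autosomes = "chr1")
scan <- pbe_scan(gm)
table(scan$tier)
#> extreme    none outlier
#>       3   16843       5
```

The numbered scripts under `analysis/` run the same stages end to end
(`01_simulate.R` … `05_deconvolution.R`), writing stage tables under
`results/` and printing what each stage found.

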