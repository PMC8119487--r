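# artakit

Genotype–phenotype analysis of autosomal dominant progressive hearing loss
(ADHL), for clinical geneticists and audiology researchers working with
multigenerational families.

Families with dominant, postlingual, progressive sensorineural hearing loss
pose two linked questions: *how fast does hearing deteriorate under a given
variant*, and *is the variant causative*. `artakit` implements the standard
analysis chain for both:

* **ARTA / ATD** — Age-Related Typical Audiograms by cross-sectional
  ordinary least squares of binaural threshold on age, per frequency:
  `y(f) = β₀(f) + β₁(f)·age`, where the slope `β₁(f)` is the annual
  threshold deterioration (ATD, dB/year), with a two-sided t-test of
  `β₁ = 0` and predicted thresholds at decade ages 10–80.
* **Threshold feature arrays** — the ARTA grid tallied by hearing-loss
  degree (normal/mild/moderate/severe/profound at ≤20 / 21–40 / 41–70 /
  71–90 / >90 dB HL) × frequency band (low/mid/high), compared between
  variants with a chi-square goodness-of-fit test with sparse-cell pooling.
* **Variant evidence** — PM2 (rarity across population databases), PP1
  (co-segregation graded by concordant informative meioses on a pedigree,
  proband excluded) and the ACMG/AMP combining rules to a final class.
* **Synthetic cohorts** — a seeded gene-dropping simulator producing
  multigenerational dominant families with progressive, 5-dB-quantized,
  noise-perturbed audiograms and ground truth, so the full pipeline is
  testable without patient data.

Audiometric units throughout: frequencies in kHz, ages in decimal years,
thresholds in dB HL (higher = worse).

## Worked example

Simulate a four-family cohort under the package's average progression
profile, fit the ARTA and inspect the deterioration per frequency:

```r
library(artakit)

cohort <- simulate_cohort(cohort_config(seed = 42))
fit <- fit_arta(arta_observations(cohort))
fit
#> <arta_model> 6 frequencies, 8 prediction ages, alpha = 0.05
#>   freq_khz slope     se  p_value  n significant
#> 1     0.25 0.806 0.0204 5.63e-56 86        TRUE
#> 2     0.50 0.761 0.0228 3.22e-50 86        TRUE
#> 3     1.00 0.714 0.0218 1.30e-49 86        TRUE
#> 4     2.00 0.656 0.0208 3.02e-48 86        TRUE
#> 5     4.00 0.636 0.0228 2.70e-44 86        TRUE
#> 6     8.00 0.574 0.0207 5.40e-44 86        TRUE
```

Each row is one frequency's regression over the 86 pooled binaural
thresholds of affected carriers: the slope is the ATD in dB/year (here
0.57–0.81, bracketing the generating profile's 0.61–0.75), `p_value` tests
zero progression, and `significant` applies the 0.05 cutoff — progression is
significant at every frequency. `plot_arta(fit)` draws the classic inverted
clinical audiogram, one line per decade of age.

Summarise the grid as a feature array and test it against the pattern a
fast-progressing variant would produce:

```r
arr <- build_feature_array(fit)
arr
#> <feature_array> total = 48 points
#>           band
#> degree     lf mf hf
#>   normal    1  0  0
#>   mild      5  3  0
#>   moderate  8  9  9
#>   severe    2  4  6
#>   profound  0  0  1

fast <- build_feature_array(profile_arta(progression_profiles()$asp185asn))
compare_feature_arrays(arr, fast)[c("chi2", "df", "p", "different")]
#> $chi2      29.9
#> $df        10
#> $p         0.000898
#> $different TRUE
```

All 48 grid points (8 ages × 6 frequencies) land in degree × band cells; the
chi-square test says this cohort's pattern differs from the fast profile's
(p ≈ 0.0009 < 0.05).

Classify a variant from the bundled synthetic family fixtures (four
4-generation ADHL pedigrees with genotypes and a population-frequency
table):

```r
ext <- function(...) system.file("extdata", ..., package = "artakit")
fam <- read_pedigree(ext("family2_synthetic.ped"),
                     ext("family2_genotypes_synthetic.csv"))
recs <- read_frequency_table(ext("variant_frequencies.csv"))
cls <- classify_variant(fam$pedigree, fam$observation,
                        recs[[fam$observation$variant_id]])
cls
#> <variant_classification> c.553G>A (family FAM2): likely_pathogenic
#>   criteria: PM2(moderate), PP1(strong)
cls$rationale$PP1
#> "7/7 concordant informative meioses (proband excluded) -> strong"

cohort_prevalence(4, 102)$percent_rounded
#> 4
```

The variant is absent from all three databases (PM2), co-segregates over 7
informative meioses (PP1 applied as strong), and the ACMG rules combine
these to *likely pathogenic*; 4 such findings among 102 screened families is
a prevalence of 3.92%, i.e. about 4% of dominant hearing-loss families.

## Command line

A thin wrapper (`inst/cli/artakit`) drives the same functions:

```sh
Rscript inst/cli/artakit simulate --config inst/extdata/example_config.yaml --out cohort --seed 42
Rscript inst/cli/artakit arta --config my_run.yaml --out arta_out
Rscript inst/cli/artakit classify-variant --config families.yaml --out reports
```

Every run writes a `run_log.txt` with the effective parameters (band map,
PP1 tiers, cutoffs, seed), so runs are reproducible from config + seed.

## Further reading

The methods vignette (`vignettes/arta-methods.Rmd`) documents the model and
its assumptions, every tunable parameter with units and defaults, the
synthetic-data generator's scope and blind spots, numerical edge-case
policies, and known limitations.
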