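test_that("cohort simulation is deterministic under a fixed seed", {
  cfg <- cohort_config(seed = 123)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$audiograms, c2$audiograms)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(cohort_config(seed = 124))
  expect_false(identical(c1$audiograms, c3$audiograms))
  expect_error(cohort_config(), "seed is mandatory")
})

test_that("measured thresholds are 5-dB multiples inside the audiometer range", {
  co <- simulate_cohort(cohort_config(seed = 5))
  thr <- co$audiograms$threshold_db
  expect_true(all(thr %% 5 == 0))
  expect_true(all(thr >= -10 & thr <= 120))
})

test_that("noise-free carriers at onset measure their baseline, flat profiles never progress", {
  p <- progression_profile("flat0", 20,
                           baseline_db = c(`1` = 32, `4` = 47),
                           atd_db_per_year = c(`1` = 0, `4` = 0),
                           noise_sd_db = 0)
  at_onset <- simulate_audiogram(20, TRUE, p)$left$thresholds
  expect_equal(unname(at_onset), c(30, 45)) # baseline rounded to 5 dB
  later <- simulate_audiogram(70, TRUE, p)$right$thresholds
  expect_equal(later, at_onset) # zero slope: identical at any age
  # before onset there is no progression either
  pre <- simulate_audiogram(10, TRUE, p)$left$thresholds
  expect_equal(pre, at_onset)
})

test_that("transmission from carriers is Mendelian in unascertained families", {
  set.seed(77)
  cfg <- cohort_config(mean_offspring = 3, seed = 77)
  n_trans <- 0; n_carrier <- 0
  while (n_trans < 2000) {
    sim <- simulate_pedigree(cfg, ascertain = FALSE)
    ind <- sim$pedigree$individuals
    carr <- sim$carriers
    for (k in seq_len(nrow(ind))) {
      parents <- c(ind$father[k], ind$mother[k])
      parents <- parents[!is.na(parents)]
      if (any(carr[parents])) {
        n_trans <- n_trans + 1
        n_carrier <- n_carrier + carr[[ind$id[k]]]
      }
    }
  }
  frac <- n_carrier / n_trans
  se <- sqrt(0.25 / n_trans)
  expect_lt(abs(frac - 0.5), 3 * se)
})

test_that("emitted families span at least three generations with a valid proband", {
  for (s in 1:5) {
    co <- simulate_cohort(cohort_config(seed = s))
    for (fam in names(co$pedigrees)) {
      ped <- co$pedigrees[[fam]]
      expect_gte(pedigree_generations(ped), 3)
      expect_false(is.null(ped$proband_id))
      expect_equal(unname(co$observations[[fam]]$genotypes[ped$proband_id]),
                   "het")
      aff_ids <- ped$individuals$id[ped$individuals$affected == "yes"]
      expect_true(all(co$truth[[fam]]$carriers[aff_ids]))
    }
  }
})

test_that("written cohorts read back identically", {
  co <- simulate_cohort(cohort_config(seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$audiograms), co$audiograms)
  for (fam in names(co$pedigrees)) {
    expect_equal(back$pedigrees[[fam]]$individuals[, 1:5],
                 co$pedigrees[[fam]]$individuals[, 1:5])
    expect_equal(back$pedigrees[[fam]]$proband_id,
                 co$pedigrees[[fam]]$proband_id)
    expect_equal(back$observations[[fam]]$genotypes,
                 co$observations[[fam]]$genotypes)
    expect_equal(unlist(back$truth[[fam]]$atd_db_per_year),
                 co$truth[[fam]]$atd_db_per_year)
  }
})

test_that("ARTA fits on simulated cohorts recover the generating slopes", {
  rec <- evaluate_slope_recovery(n_rep = 60, seed = 2026)
  # estimate within +/- 2 SE of truth roughly 95% of the time, per frequency
  expect_true(all(rec$per_freq$coverage >= 0.85))
  expect_true(all(rec$per_freq$significance_rate >= 0.95))
  expect_gt(rec$mean_n, 40) # cohorts sized near the 81-threshold design
})

test_that("non-carrier slope confidence intervals cover zero", {
  set.seed(314)
  seeds <- sample.int(1e6, 100)
  covered <- 0; total <- 0
  for (s in seeds) {
    co <- simulate_cohort(cohort_config(seed = s))
    aud <- co$audiograms
    noncar <- unlist(lapply(names(co$pedigrees), function(fam) {
      carr <- co$truth[[fam]]$carriers
      paste(fam, names(carr)[!carr])
    }))
    aud <- aud[paste(aud$family_id, aud$subject_id) %in% noncar, ]
    bin <- binaural_table(aud)
    bin$subject_id <- paste(bin$family_id, bin$subject_id)
    fit <- fit_arta(bin)
    ok <- fit$atd$fittable
    covered <- covered + sum(abs(fit$atd$slope[ok]) <= 2 * fit$atd$se[ok])
    total <- total + sum(ok)
  }
  expect_gte(covered / total, 0.9)
})

test_that("the fast-progressing profile separates from the average pattern", {
  sep <- evaluate_pattern_separation(n_seeds = 40, seed = 7)
  expect_gt(sep$fraction_different, 0.5)
})
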