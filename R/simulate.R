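#' Hearing-loss progression profile
#'
#' Parameters of the linear progression model: a carrier's true threshold at
#' frequency f and age a is `baseline_db[f] + atd_db_per_year[f] * max(0, a -
#' onset_age_years)`. Measured thresholds add per-ear Gaussian test-retest
#' noise, are clipped to the audiometer range and quantized to 5 dB (the
#' resolution of the 10-down/5-up threshold search).
#'
#' @param variant_label Profile name.
#' @param onset_age_years Age at onset (years).
#' @param baseline_db Named numeric vector, threshold at onset per frequency
#'   (kHz).
#' @param atd_db_per_year Named numeric vector, annual threshold
#'   deterioration per frequency; non-negative.
#' @param noise_sd_db Per-ear measurement noise SD in dB (default 7).
#' @param audiometer_range Output limits in dB HL (default c(-10, 120)).
#' @return Object of class `progression_profile`.
#' @export
progression_profile <- function(variant_label, onset_age_years, baseline_db,
                                atd_db_per_year, noise_sd_db = 7,
                                audiometer_range = c(-10, 120)) {
  stopifnot(onset_age_years >= 0, noise_sd_db >= 0,
            length(audiometer_range) == 2)
  if (!identical(names(baseline_db), names(atd_db_per_year))) {
    stop("baseline_db and atd_db_per_year must share frequency names")
  }
  if (any(atd_db_per_year < 0)) stop("atd must be non-negative per frequency")
  structure(list(variant_label = as.character(variant_label),
                 onset_age_years = onset_age_years,
                 baseline_db = baseline_db,
                 atd_db_per_year = atd_db_per_year,
                 noise_sd_db = noise_sd_db,
                 audiometer_range = audiometer_range),
            class = "progression_profile")
}

#' Bundled progression profiles
#'
#' Default profiles for dominant progressive hearing loss: an average profile
#' (ATD 0.75 dB/year at 0.25/0.5 kHz falling to 0.61 at 8 kHz) and three
#' variant-specific profiles spanning the reported per-variant ATD ranges
#' (0.83--1.72 for the fast-progressing profile, 0.88--1.08 and 0.59--1.03
#' for the slower ones). Slopes at interior frequencies interpolate the range
#' endpoints; baselines are illustrative package defaults chosen to give
#' mild low/mid-frequency and moderate high-frequency loss early in life.
#'
#' @param noise_sd_db Per-ear measurement noise SD (default 7 dB).
#' @return Named list of [progression_profile()] objects: `average`,
#'   `ser178leu`, `asp185asn`, `his487leu`.
#' @export
progression_profiles <- function(noise_sd_db = 7) {
  f <- c("0.25", "0.5", "1", "2", "4", "8")
  nm <- function(x) stats::setNames(x, f)
  list(
    average = progression_profile(
      "average", 20,
      baseline_db = nm(c(30, 30, 35, 40, 50, 55)),
      atd_db_per_year = nm(c(0.75, 0.75, 0.72, 0.69, 0.65, 0.61)),
      noise_sd_db = noise_sd_db),
    ser178leu = progression_profile(
      "ser178leu", 19.5,
      baseline_db = nm(c(25, 25, 30, 35, 40, 40)),
      atd_db_per_year = nm(c(0.95, 1.00, 1.08, 1.00, 0.88, 0.92)),
      noise_sd_db = noise_sd_db),
    asp185asn = progression_profile(
      "asp185asn", 16.7,
      baseline_db = nm(c(30, 35, 40, 45, 55, 60)),
      atd_db_per_year = nm(c(0.83, 1.10, 1.45, 1.72, 1.40, 1.10)),
      noise_sd_db = noise_sd_db),
    his487leu = progression_profile(
      "his487leu", 35,
      baseline_db = nm(c(30, 30, 35, 40, 45, 50)),
      atd_db_per_year = nm(c(0.95, 1.03, 0.90, 0.75, 0.59, 0.70)),
      noise_sd_db = noise_sd_db)
  )
}

# Normal-hearing baseline for non-carriers (flat, slightly raised at high
# frequencies), no progression.
noncarrier_baseline <- function(freqs) {
  stats::setNames(ifelse(as.numeric(freqs) >= 4, 10, 5), freqs)
}

#' Cohort simulation configuration
#'
#' @param n_families Number of families.
#' @param generations Pedigree depth (>= 3).
#' @param mean_offspring Mean children per reproducing couple (>= 1).
#' @param genotype_missing Probability an individual is not genotyped.
#' @param audiometry_missing Probability an individual has no audiometry.
#' @param visits Pure-tone test sessions per tested subject.
#' @param seed Mandatory RNG seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_families = 4, generations = 4,
                          mean_offspring = 3.2, genotype_missing = 0.05,
                          audiometry_missing = 0.1, visits = 3, seed) {
  if (missing(seed) || is.null(seed)) stop("cohort_config: seed is mandatory")
  stopifnot(n_families >= 1, generations >= 3, mean_offspring >= 1,
            genotype_missing >= 0, genotype_missing < 1,
            audiometry_missing >= 0, audiometry_missing < 1, visits >= 1)
  structure(list(n_families = n_families, generations = generations,
                 mean_offspring = mean_offspring,
                 genotype_missing = genotype_missing,
                 audiometry_missing = audiometry_missing,
                 visits = visits, seed = as.integer(seed)),
            class = "cohort_config")
}

# One gene-dropped family: founder het carrier, offspring inherit with
# probability 1/2, married-in individuals are ref. Ages fall by ~27 years
# per generation. Returns raw vectors, not yet a pedigree object.
drop_family <- function(cfg, onset_age) {
  G <- cfg$generations
  gen_age <- function(g) max(5, stats::rnorm(1, 22 + 27 * (G - g), 3))
  id <- character(0); father <- character(0); mother <- character(0)
  sex <- character(0); carrier <- logical(0); age <- numeric(0)
  gen <- integer(0)
  add <- function(i, f, m, s, c, a, g) {
    id <<- c(id, i); father <<- c(father, f); mother <<- c(mother, m)
    sex <<- c(sex, s); carrier <<- c(carrier, c); age <<- c(age, a)
    gen <<- c(gen, g)
  }
  add("g1i1", NA, NA, "male", TRUE, gen_age(1), 1L)
  add("g1i2", NA, NA, "female", FALSE, gen_age(1), 1L)
  couples <- list(c("g1i1", "g1i2"))
  for (g in 2:G) {
    next_couples <- list()
    k <- 0L
    for (cp in couples) {
      n_kids <- 1L + stats::rpois(1, cfg$mean_offspring - 1)
      dad <- if (sex[match(cp[1], id)] == "male") cp[1] else cp[2]
      mom <- setdiff(cp, dad)
      parent_carrier <- carrier[match(dad, id)] || carrier[match(mom, id)]
      for (j in seq_len(n_kids)) {
        k <- k + 1L
        cid <- sprintf("g%di%d", g, k)
        csex <- sample(c("male", "female"), 1)
        ccar <- parent_carrier && stats::runif(1) < 0.5
        add(cid, dad, mom, csex, ccar, gen_age(g), g)
        reproduces <- g < G &&
          stats::runif(1) < (if (ccar) 0.9 else 0.35)
        if (reproduces) {
          k <- k + 1L
          sid <- sprintf("g%di%d", g, k)
          ssex <- if (csex == "male") "female" else "male"
          add(sid, NA, NA, ssex, FALSE, age[match(cid, id)] +
                stats::rnorm(1, 0, 3), g)
          next_couples[[length(next_couples) + 1L]] <- c(cid, sid)
        }
      }
    }
    couples <- next_couples
    if (length(couples) == 0 && g < G) break
  }
  affected <- ifelse(carrier & age >= onset_age, "yes", "no")
  data.frame(id = id, father = father, mother = mother, sex = sex,
             affected = affected, age_years = age, carrier = carrier,
             gen = gen, stringsAsFactors = FALSE)
}

#' Simulate an autosomal-dominant family
#'
#' Gene-drops a heterozygous founder variant through a multigenerational
#' pedigree: each offspring of a carrier inherits the variant with
#' probability 1/2, married-in individuals are non-carriers, and affection
#' status is carrier AND age >= onset (full penetrance above onset). With
#' `ascertain = TRUE` (default) families are redrawn until affected carriers
#' span at least 3 generations and a genotyped affected carrier exists in the
#' youngest affected generation to serve as proband, mirroring how dominant
#' hearing-loss families are recruited.
#'
#' Uses R's global RNG stream; seed it (e.g. via [simulate_cohort()] or
#' `set.seed`) for reproducibility.
#'
#' @param cfg A [cohort_config()].
#' @param family_id Family label.
#' @param onset_age Onset age used for affection status (years).
#' @param variant_id Variant label for the genotype observation.
#' @param ascertain Redraw until the family meets the recruitment criteria.
#' @param max_tries Redraw limit (default 100).
#' @return List with `pedigree`, `observation` (genotypes with missingness
#'   applied), `carriers` (named logical truth) and `ages` (named numeric).
#' @export
simulate_pedigree <- function(cfg, family_id = "FAM1", onset_age = 20,
                              variant_id = "variant", ascertain = TRUE,
                              max_tries = 100) {
  stopifnot(inherits(cfg, "cohort_config"))
  for (try in seq_len(if (ascertain) max_tries else 1L)) {
    fam <- drop_family(cfg, onset_age)
    geno <- ifelse(fam$carrier, "het", "ref")
    untyped <- stats::runif(nrow(fam)) < cfg$genotype_missing
    geno[untyped] <- "untyped"
    aff_gens <- unique(fam$gen[fam$affected == "yes"])
    candidates <- fam$id[fam$affected == "yes" & geno == "het"]
    ok <- length(aff_gens) >= 3 && length(candidates) > 0
    if (ok || !ascertain) break
  }
  proband <- if (length(candidates)) {
    cand <- fam[fam$id %in% candidates, ]
    cand$id[which.max(cand$gen)]
  } else {
    NULL
  }
  ped <- pedigree(fam[, c("id", "father", "mother", "sex", "affected",
                          "age_years")],
                  proband_id = proband, family_id = family_id)
  obs <- variant_observation(variant_id, stats::setNames(geno, fam$id))
  list(pedigree = ped, observation = obs,
       carriers = stats::setNames(fam$carrier, fam$id),
       ages = stats::setNames(fam$age_years, fam$id))
}

#' Simulate one pure-tone test session (both ears)
#'
#' True thresholds follow the profile's linear progression (carriers) or a
#' flat normal-hearing baseline (non-carriers). Both ears share the true
#' value; measurement noise is independent per ear. Order of operations:
#' clip the true value to the audiometer range, add Normal(0, noise_sd)
#' noise, clip again, round to the nearest 5 dB. Frequencies whose noisy
#' value exceeded the audiometer maximum are flagged censored.
#'
#' @param subject_age Age at testing (years, >= 0).
#' @param carrier Is the subject a variant carrier?
#' @param profile A [progression_profile()].
#' @param subject_id,family_id Identifiers for the emitted audiograms.
#' @return List with `left` and `right` [ear_audiogram()] objects.
#' @export
simulate_audiogram <- function(subject_age, carrier, profile,
                               subject_id = "S1", family_id = "FAM1") {
  stopifnot(inherits(profile, "progression_profile"), subject_age >= 0)
  freqs <- names(profile$baseline_db)
  rng <- profile$audiometer_range
  true <- if (carrier) {
    profile$baseline_db + profile$atd_db_per_year *
      max(0, subject_age - profile$onset_age_years)
  } else {
    noncarrier_baseline(freqs)
  }
  true <- pmin(pmax(as.numeric(true), rng[1]), rng[2])
  one_ear <- function(ear) {
    noisy <- true + stats::rnorm(length(true), 0, profile$noise_sd_db)
    censored <- noisy > rng[2]
    clipped <- pmin(pmax(noisy, rng[1]), rng[2])
    measured <- round(clipped / 5) * 5
    ear_audiogram(subject_id, family_id, ear, subject_age,
                  stats::setNames(measured, freqs), censored = censored)
  }
  list(left = one_ear("left"), right = one_ear("right"))
}

#' Simulate a multigenerational hearing-loss cohort
#'
#' Generates `cfg$n_families` dominant families (profiles recycled across
#' families), audiometry for available subjects (multiple visits, both ears)
#' and genotype observations, together with the ground truth needed for
#' parameter-recovery tests. Fully deterministic given `cfg$seed`.
#'
#' Visits are spaced 4 years apart ending at the subject's current age;
#' carrier visits predating onset are dropped (patients are tested once
#' hearing loss is present).
#'
#' @param cfg A [cohort_config()].
#' @param profiles List of [progression_profile()] objects (>= 1).
#' @return Object of class `adhl_cohort`: list with `audiograms` (long data
#'   frame: subject_id, family_id, ear, age_years, freq_khz, threshold_db,
#'   censored), `pedigrees`, `observations`, `truth`.
#' @export
simulate_cohort <- function(cfg, profiles = progression_profiles()["average"]) {
  stopifnot(inherits(cfg, "cohort_config"), length(profiles) >= 1)
  set.seed(cfg$seed)
  pedigrees <- list()
  observations <- list()
  truth <- list()
  rows <- vector("list", cfg$n_families)

  for (f in seq_len(cfg$n_families)) {
    profile <- profiles[[((f - 1L) %% length(profiles)) + 1L]]
    fam_id <- sprintf("FAM%d", f)
    sim <- simulate_pedigree(cfg, family_id = fam_id,
                             onset_age = profile$onset_age_years,
                             variant_id = profile$variant_label)
    pedigrees[[fam_id]] <- sim$pedigree
    observations[[fam_id]] <- sim$observation
    truth[[fam_id]] <- list(profile = profile$variant_label,
                            onset_age_years = profile$onset_age_years,
                            atd_db_per_year = profile$atd_db_per_year,
                            baseline_db = profile$baseline_db,
                            carriers = sim$carriers)
    ids <- names(sim$carriers)
    tested <- ids[stats::runif(length(ids)) >= cfg$audiometry_missing]
    fam_rows <- list()
    for (s in tested) {
      a0 <- sim$ages[[s]]
      visit_ages <- a0 - 4 * (seq_len(cfg$visits) - 1)
      visit_ages <- visit_ages[visit_ages >= 5]
      if (sim$carriers[[s]]) {
        visit_ages <- visit_ages[visit_ages >= profile$onset_age_years]
      }
      for (a in visit_ages) {
        pair <- simulate_audiogram(a, sim$carriers[[s]], profile,
                                   subject_id = s, family_id = fam_id)
        for (e in pair) {
          nf <- length(e$thresholds)
          fam_rows[[length(fam_rows) + 1L]] <- list(
            subject_id = rep(e$subject_id, nf), ear = rep(e$ear, nf),
            age_years = rep(e$age_years, nf),
            freq_khz = as.numeric(names(e$thresholds)),
            threshold_db = as.numeric(e$thresholds),
            censored = as.logical(e$censored))
        }
      }
    }
    rows[[f]] <- if (length(fam_rows)) {
      cols <- lapply(stats::setNames(nm = names(fam_rows[[1]])), function(cn) {
        unlist(lapply(fam_rows, `[[`, cn), use.names = FALSE)
      })
      data.frame(subject_id = cols$subject_id, family_id = fam_id,
                 ear = cols$ear, age_years = cols$age_years,
                 freq_khz = cols$freq_khz, threshold_db = cols$threshold_db,
                 censored = cols$censored, stringsAsFactors = FALSE)
    } else {
      NULL
    }
  }
  audiograms <- do.call(rbind, rows)
  rownames(audiograms) <- NULL
  structure(list(audiograms = audiograms, pedigrees = pedigrees,
                 observations = observations, truth = truth,
                 config = cfg),
            class = "adhl_cohort")
}

#' Binaural observations of affected carriers, ready for ARTA fitting
#'
#' Computes binaural mean thresholds per (subject, test age, frequency) and
#' keeps affected variant carriers only, matching the clinical convention of
#' pooling patients' audiograms for cross-sectional regression. Frequencies
#' measured in one ear only are dropped unless `include_single_ear = TRUE`.
#'
#' @param cohort An `adhl_cohort`.
#' @param include_single_ear Admit single-ear thresholds as-is.
#' @return Long data frame with subject_id, age_years, freq_khz,
#'   threshold_db.
#' @export
arta_observations <- function(cohort, include_single_ear = FALSE) {
  stopifnot(inherits(cohort, "adhl_cohort"))
  aud <- cohort$audiograms
  affected_carrier <- unlist(lapply(names(cohort$pedigrees), function(fam) {
    ped <- cohort$pedigrees[[fam]]$individuals
    carr <- cohort$truth[[fam]]$carriers
    ids <- ped$id[ped$affected == "yes" & carr[ped$id]]
    paste(fam, ids)
  }))
  keep <- paste(aud$family_id, aud$subject_id) %in% affected_carrier
  aud <- aud[keep & !is.na(aud$threshold_db), , drop = FALSE]
  if (nrow(aud) == 0) {
    return(data.frame(subject_id = character(0), age_years = numeric(0),
                      freq_khz = numeric(0), threshold_db = numeric(0)))
  }
  agg <- stats::aggregate(
    threshold_db ~ family_id + subject_id + age_years + freq_khz,
    data = aud, FUN = mean)
  cnt <- stats::aggregate(
    threshold_db ~ family_id + subject_id + age_years + freq_khz,
    data = aud, FUN = length)
  if (!include_single_ear) {
    agg <- agg[cnt$threshold_db == 2, , drop = FALSE]
  }
  agg$subject_id <- paste(agg$family_id, agg$subject_id)
  agg[, c("subject_id", "age_years", "freq_khz", "threshold_db")]
}

#' Noise-free ARTA implied by a progression profile
#'
#' The regression line a cross-sectional fit targets under a profile:
#' threshold(a, f) = baseline(f) + atd(f) * (a - onset). Useful as a fixed
#' reference for feature-array comparisons.
#'
#' @param profile A [progression_profile()].
#' @param prediction_ages Ages of the ARTA grid (default 10--80 by decades).
#' @param alpha Significance level carried into the model object.
#' @return An `arta_model` with exact slopes and intercepts.
#' @export
profile_arta <- function(profile, prediction_ages = seq(10, 80, by = 10),
                         alpha = 0.05) {
  stopifnot(inherits(profile, "progression_profile"))
  freqs <- as.numeric(names(profile$baseline_db))
  slope <- as.numeric(profile$atd_db_per_year)
  intercept <- as.numeric(profile$baseline_db) -
    slope * profile$onset_age_years
  predicted <- outer(prediction_ages, seq_along(freqs), function(a, j) {
    intercept[j] + slope[j] * a
  })
  dimnames(predicted) <- list(age = as.character(prediction_ages),
                              freq_khz = as.character(freqs))
  atd <- data.frame(freq_khz = freqs, slope = slope, intercept = intercept,
                    se = 0, p_value = ifelse(slope == 0, 1, 0),
                    n = NA_integer_, significant = slope != 0,
                    fittable = TRUE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  structure(list(atd = atd, predicted = predicted,
                 prediction_ages = prediction_ages, grid = freqs,
                 alpha = alpha),
            class = "arta_model")
}
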