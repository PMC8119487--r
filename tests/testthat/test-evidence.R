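test_that("PM2 rarity holds for absent or near-zero variants only", {
  zero <- population_frequency_record("v", c(gnomAD = 0, UK10K = 0, EVS = 0))
  expect_true(evaluate_pm2(zero)$met)
  absent <- population_frequency_record("v", c(gnomAD = NA, UK10K = NA))
  expect_true(evaluate_pm2(absent)$met)
  common <- population_frequency_record("v", c(gnomAD = 0.01, UK10K = 0))
  res <- evaluate_pm2(common)
  expect_false(res$met)
  expect_match(res$rationale, "gnomAD")
  # the cutoff is configurable
  borderline <- population_frequency_record("v", c(gnomAD = 1e-4))
  expect_false(evaluate_pm2(borderline)$met)
  expect_true(evaluate_pm2(borderline, max_af = 1e-3)$met)
  expect_error(population_frequency_record("v", numeric(0)), "non-empty")
})

test_that("segregation counting handles a trio and a deep family as enumerated by hand", {
  # affected het parent with one affected het child; parent is the proband,
  # so the only countable transmission is parent -> child
  trio <- pedigree(data.frame(
    id = c("p1", "p2", "c1"),
    father = c(NA, NA, "p1"), mother = c(NA, NA, "p2"),
    sex = c("male", "female", "female"),
    affected = c("yes", "no", "yes")), proband_id = "p1")
  obs <- variant_observation("v", c(p1 = "het", p2 = "ref", c1 = "het"))
  seg <- count_segregations(trio, obs)
  expect_equal(seg$n_informative, 1)
  expect_equal(seg$n_concordant, 1)
  expect_length(seg$discordants, 0)

  # three generations, 7 genotyped het affected descendants of a het founder;
  # proband excluded leaves 6 concordant transmissions
  ids <- c("f", "s", paste0("d", 1:7))
  deep <- pedigree(data.frame(
    id = ids,
    father = c(NA, NA, rep("f", 4), rep("d1", 3)),
    mother = c(NA, NA, rep("s", 4), NA, NA, NA),
    sex = c("male", "female", rep("male", 7)),
    affected = c("yes", "no", rep("yes", 7))), proband_id = "d7")
  g <- setNames(c("het", "ref", rep("het", 7)), ids)
  seg <- count_segregations(deep, variant_observation("v", g))
  expect_equal(seg$n_concordant, 6)
  expect_equal(seg$n_informative, 6)
})

test_that("unaffected carriers are discordant unless below onset age", {
  ped <- pedigree(data.frame(
    id = c("p", "m", "c1", "c2"),
    father = c(NA, NA, "p", "p"), mother = c(NA, NA, "m", "m"),
    sex = c("male", "female", "male", "female"),
    affected = c("yes", "no", "no", "yes"),
    age_years = c(55, 53, 12, 30)), proband_id = "c2")
  obs <- variant_observation("v", c(p = "het", m = "ref", c1 = "het",
                                    c2 = "het"))
  full <- count_segregations(ped, obs, penetrance_mode = "full")
  expect_equal(full$discordants, "c1")
  expect_equal(full$n_informative, 1) # proband excluded
  aged <- count_segregations(ped, obs, penetrance_mode = "age_dependent",
                             onset_age = 18)
  expect_length(aged$discordants, 0)
  expect_equal(aged$n_informative, 0)
  expect_error(count_segregations(ped, obs,
                                  penetrance_mode = "age_dependent"),
               "onset_age")
  # proband must be a genotyped carrier
  bad <- variant_observation("v", c(p = "het", c2 = "ref"))
  expect_error(count_segregations(ped, bad), "not a genotyped het")
})

test_that("obligate-carrier inference bridges an untyped transmitting ancestor", {
  ped <- pedigree(data.frame(
    id = c("g", "gs", "m", "ms", "c"),
    father = c(NA, NA, "g", NA, "m"),
    mother = c(NA, NA, "gs", NA, "ms"),
    sex = c("male", "female", "male", "female", "male"),
    affected = c("yes", "no", "yes", "no", "yes")), proband_id = "c")
  obs <- variant_observation("v", c(g = "het", m = "untyped", ms = "ref",
                                    c = "het"))
  off <- count_segregations(ped, obs)
  on <- count_segregations(ped, obs, infer_obligate = TRUE)
  expect_equal(off$n_informative, 0)  # c's parents untyped/ref, m's edge is m only
  expect_equal(on$n_concordant, 1)    # m inferred het -> m counts as offspring of g
  expect_equal(on$n_informative, 1)
})

test_that("PP1 grading follows the 3/5/7 tiers and the discordance cap", {
  expect_equal(grade_pp1(7), "strong")
  expect_equal(grade_pp1(2), "none")
  expect_equal(grade_pp1(5, discordants_empty = FALSE), "none")
  expect_equal(grade_pp1(3), "supporting")
  expect_equal(grade_pp1(5), "moderate")
  expect_error(grade_pp1(-1), "non-negative")
  # monotone non-decreasing in the concordant count
  order_ <- c(none = 0, supporting = 1, moderate = 2, strong = 3)
  g <- order_[vapply(0:10, grade_pp1, character(1))]
  expect_true(all(diff(g) >= 0))
  # custom tiers are honoured
  expect_equal(grade_pp1(4, tiers = c(supporting = 2, moderate = 4, strong = 9)),
               "moderate")
})

test_that("ACMG combining reproduces the standard rule table", {
  cls <- function(codes, strengths = NULL) {
    combine_acmg(acmg_evidence(codes, strengths))
  }
  expect_equal(cls(c("PM2", "PP1"), c(NA, "strong")), "likely_pathogenic")
  expect_equal(cls(character(0)), "VUS")
  expect_equal(cls(c("PVS1", "PS1")), "pathogenic")
  expect_equal(cls(c("PVS1", "PM2")), "likely_pathogenic")
  expect_equal(cls(c("PS1", "PS2")), "pathogenic")
  expect_equal(cls(c("PM1", "PM2", "PM4")), "likely_pathogenic")
  expect_equal(cls(c("PM2", "PP1", "PP2", "PP3", "PP4")), "likely_pathogenic")
  expect_equal(cls(c("PM2", "PP3")), "VUS")
  expect_equal(cls("BA1"), "benign")
  expect_equal(cls(c("BS1", "BS2")), "benign")
  expect_equal(cls(c("BS1", "BP1")), "likely_benign")
  expect_equal(cls(c("BP1", "BP4")), "likely_benign")
  # conflicting evidence collapses to VUS
  expect_equal(cls(c("PVS1", "PS1", "BA1")), "VUS")
  expect_error(acmg_evidence("XX9"), "unknown ACMG criterion")
  expect_error(acmg_evidence(c("PM2", "PM2")), "duplicated")
})

test_that("adding pathogenic evidence never moves the class toward benign", {
  rank <- c(benign = 1, likely_benign = 2, VUS = 3,
            likely_pathogenic = 4, pathogenic = 5)
  pool <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PM4", "PP1", "PP2", "PP3")
  set.seed(13)
  for (i in 1:40) {
    base <- sample(pool, sample(0:4, 1))
    extra <- sample(setdiff(pool, base), 1)
    r0 <- rank[combine_acmg(acmg_evidence(base))]
    r1 <- rank[combine_acmg(acmg_evidence(c(base, extra)))]
    expect_gte(r1, r0)
  }
})

test_that("segregation counts match brute-force edge enumeration on random pedigrees", {
  set.seed(31)
  cfg <- cohort_config(generations = 3, mean_offspring = 2, seed = 31)
  tried <- 0
  for (i in 1:40) {
    sim <- simulate_pedigree(cfg, onset_age = 18, ascertain = FALSE)
    ped <- sim$pedigree
    if (nrow(ped$individuals) > 15) next
    g <- sim$observation$genotypes
    hets <- names(g)[g == "het"]
    if (length(hets) == 0) next
    proband <- sample(hets, 1)
    ped$proband_id <- proband
    tried <- tried + 1
    mine <- count_segregations(ped, sim$observation)
    oracle <- segregation_oracle(ped, sim$observation, proband)
    expect_equal(mine$n_informative, oracle$n_informative)
    expect_equal(mine$n_concordant, oracle$n_concordant)
    expect_setequal(mine$discordants, oracle$discordants)
  }
  expect_gte(tried, 10)
})

test_that("pedigree validation rejects broken graphs", {
  base <- data.frame(id = c("a", "b"), father = c(NA, "a"),
                     mother = c(NA, NA), sex = c("male", "male"),
                     affected = c("yes", "no"))
  expect_s3_class(pedigree(base), "pedigree")
  dangling <- base; dangling$father[2] <- "ghost"
  expect_error(pedigree(dangling), "ghost")
  cyclic <- data.frame(id = c("a", "b"), father = c("b", "a"),
                       mother = c(NA, NA), sex = c("male", "male"),
                       affected = c("yes", "no"))
  expect_error(pedigree(cyclic), "cyclic")
  wrongsex <- data.frame(id = c("a", "b"), father = c(NA, "a"),
                         mother = c(NA, NA), sex = c("female", "male"),
                         affected = c("yes", "no"))
  expect_error(pedigree(wrongsex), "father")
  expect_error(pedigree(base, proband_id = "zz"), "proband")
})

test_that("the bundled synthetic families classify as likely pathogenic", {
  recs <- read_frequency_table(fixture_path("variant_frequencies.csv"))
  for (i in 1:4) {
    fam <- read_pedigree(
      fixture_path(sprintf("family%d_synthetic.ped", i)),
      fixture_path(sprintf("family%d_genotypes_synthetic.csv", i)))
    cls <- classify_variant(fam$pedigree, fam$observation,
                            recs[[fam$observation$variant_id]])
    expect_equal(cls$class, "likely_pathogenic")
    expect_setequal(cls$evidence$code, c("PM2", "PP1"))
    expect_equal(cls$evidence$strength[cls$evidence$code == "PP1"], "strong")
  }
})

test_that("screening prevalence is reported as a percentage", {
  prev <- cohort_prevalence(4, 102)
  expect_equal(prev$fraction, 4 / 102)
  expect_equal(round(prev$percent, 2), 3.92)
  expect_equal(prev$percent_rounded, 4)
  expect_error(cohort_prevalence(5, 4))
})
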