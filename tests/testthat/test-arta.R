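test_that("noiseless linear data is fitted exactly and predicted on the line", {
  ages <- seq(10, 80, 10)
  obs <- data.frame(age_years = ages, freq_khz = 1,
                    threshold_db = 10 + 0.7 * ages)
  fit <- fit_arta(obs, grid = 1)
  expect_equal(fit$atd$slope, 0.7, tolerance = 1e-12)
  expect_equal(fit$atd$intercept, 10, tolerance = 1e-12)
  expect_equal(unname(fit$predicted["50", "1"]), 45, tolerance = 1e-12)
  # exact fit with nonzero slope: zero SE, p = 0
  expect_equal(fit$atd$se, 0)
  expect_equal(fit$atd$p_value, 0)
})

test_that("flat data yields zero slope with p = 1 and no significance", {
  obs <- data.frame(age_years = seq(10, 80, 10), freq_khz = 2,
                    threshold_db = 50)
  fit <- fit_arta(obs, grid = 2)
  expect_equal(fit$atd$slope, 0, tolerance = 1e-12)
  expect_equal(fit$atd$p_value, 1)
  expect_false(fit$atd$significant)
})

test_that("slope, SE and p match the closed-form OLS oracle", {
  # hand-checkable 5-point example
  obs <- data.frame(age_years = c(10, 20, 30, 40, 50), freq_khz = 1,
                    threshold_db = c(20, 30, 25, 45, 50))
  fit <- fit_arta(obs, grid = 1)
  expect_equal(fit$atd$slope, 0.75, tolerance = 1e-12)   # 750 / 1000
  expect_equal(fit$atd$intercept, 11.5, tolerance = 1e-12)
  o <- ols_oracle(obs$age_years, obs$threshold_db)
  expect_equal(fit$atd$se, o$se, tolerance = 1e-12)
  expect_equal(fit$atd$p_value, o$p, tolerance = 1e-12)

  # and on random datasets, against both the closed form and summary.lm
  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    age <- runif(n, 5, 85)
    y <- runif(n, 0, 110)
    fit <- fit_arta(data.frame(age_years = age, freq_khz = 4,
                               threshold_db = y), grid = 4)
    o <- ols_oracle(age, y)
    expect_equal(fit$atd$slope, o$slope, tolerance = 1e-10)
    expect_equal(fit$atd$se, o$se, tolerance = 1e-10)
    expect_equal(fit$atd$p_value, o$p, tolerance = 1e-10)
    sm <- summary(lm(y ~ age))$coefficients
    expect_equal(fit$atd$slope, sm["age", "Estimate"], tolerance = 1e-10)
    expect_equal(fit$atd$se, sm["age", "Std. Error"], tolerance = 1e-10)
  }
})

test_that("adding a constant shifts intercept and predictions, not the slope", {
  set.seed(7)
  age <- runif(30, 10, 80)
  y <- 15 + 0.8 * age + rnorm(30, 0, 8)
  f0 <- fit_arta(data.frame(age_years = age, freq_khz = 1, threshold_db = y),
                 grid = 1)
  f1 <- fit_arta(data.frame(age_years = age, freq_khz = 1,
                            threshold_db = y + 12), grid = 1)
  expect_equal(f1$atd$slope, f0$atd$slope, tolerance = 1e-10)
  expect_equal(f1$atd$intercept, f0$atd$intercept + 12, tolerance = 1e-10)
  expect_equal(f1$predicted, f0$predicted + 12, tolerance = 1e-10)
})

test_that("insufficient or degenerate frequencies are flagged, not dropped", {
  obs <- rbind(
    data.frame(age_years = c(20, 30, 40), freq_khz = 1,
               threshold_db = c(20, 30, 40)),
    data.frame(age_years = c(20, 30), freq_khz = 2,
               threshold_db = c(20, 30)),
    data.frame(age_years = c(25, 25, 25), freq_khz = 4,
               threshold_db = c(20, 30, 40)))
  fit <- fit_arta(obs, grid = c(1, 2, 4))
  expect_equal(fit$atd$fittable, c(TRUE, FALSE, FALSE))
  expect_equal(fit$atd$reason[2], "fewer than 3 observations")
  expect_equal(fit$atd$reason[3], "no age spread")
  expect_equal(nrow(fit$atd), 3) # unfittable frequencies remain visible
  expect_true(all(is.na(fit$predicted[, c("2", "4")])))
})

test_that("predictions increase with age whenever the slope is non-negative", {
  set.seed(99)
  for (i in 1:10) {
    age <- runif(20, 10, 80)
    y <- 10 + runif(1, 0, 2) * age + rnorm(20, 0, 5)
    fit <- fit_arta(data.frame(age_years = age, freq_khz = 1,
                               threshold_db = y), grid = 1)
    if (fit$atd$slope >= 0) {
      expect_true(all(diff(fit$predicted[, "1"]) >= 0))
    }
  }
})

test_that("binaural audiogram lists are accepted as observations", {
  mk <- function(s, a, thr) {
    structure(list(subject_id = s, family_id = "f", age_years = a,
                   thresholds = setNames(thr, c(1))),
              class = "binaural_audiogram")
  }
  obs <- list(mk("a", 20, 24), mk("b", 40, 38), mk("c", 60, 52))
  fit <- fit_arta(obs, grid = 1)
  expect_equal(fit$atd$slope, 0.7, tolerance = 1e-10)
  expect_equal(fit$atd$n, 3)
})

test_that("ARTA export writes the matrix and ATD tables", {
  obs <- data.frame(age_years = seq(10, 80, 10), freq_khz = 1,
                    threshold_db = 10 + 0.7 * seq(10, 80, 10))
  fit <- fit_arta(obs, grid = 1)
  dir <- withr::local_tempdir()
  paths <- export_arta(fit, dir)
  expect_true(all(file.exists(paths)))
  mat <- read.delim(paths[1], check.names = FALSE)
  expect_equal(mat$`1`, unname(fit$predicted[, "1"]))
})
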