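#' Slope-recovery simulation study
#'
#' Repeatedly simulates a cohort under one progression profile, fits the ARTA
#' regression to the affected carriers' binaural thresholds and checks, per
#' frequency, whether the estimated annual deterioration lies within +/- 2
#' standard errors of the generating slope and whether it is declared
#' significant at the model's alpha.
#'
#' @param n_rep Number of replicates (default 500).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param profile Generating [progression_profile()] (default the average
#'   profile).
#' @param cfg_template Arguments for [cohort_config()] besides `seed`, sized
#'   to yield roughly 81 binaural thresholds per replicate.
#' @param alpha Significance level of the slope test.
#' @return List with `per_freq` (data frame: freq_khz, true_slope,
#'   mean_slope, coverage,
#'   significance_rate), `mean_n` (mean thresholds per frequency) and
#'   `n_rep`.
#' @export
evaluate_slope_recovery <- function(n_rep = 500, seed = 1,
                                    profile = progression_profiles()$average,
                                    cfg_template = list(),
                                    alpha = 0.05) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  freqs <- as.numeric(names(profile$atd_db_per_year))
  true <- as.numeric(profile$atd_db_per_year)
  covered <- matrix(NA, n_rep, length(freqs))
  signif <- matrix(NA, n_rep, length(freqs))
  slopes <- matrix(NA_real_, n_rep, length(freqs))
  ns <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- do.call(cohort_config, c(cfg_template, list(seed = rep_seeds[r])))
    cohort <- simulate_cohort(cfg, profiles = list(profile))
    obs <- arta_observations(cohort)
    fit <- fit_arta(obs, grid = freqs, alpha = alpha)
    ok <- fit$atd$fittable
    covered[r, ok] <- abs(fit$atd$slope[ok] - true[ok]) <= 2 * fit$atd$se[ok]
    signif[r, ok] <- fit$atd$significant[ok]
    slopes[r, ok] <- fit$atd$slope[ok]
    ns[r] <- stats::median(fit$atd$n)
  }
  per_freq <- data.frame(
    freq_khz = freqs, true_slope = true,
    mean_slope = colMeans(slopes, na.rm = TRUE),
    coverage = colMeans(covered, na.rm = TRUE),
    significance_rate = colMeans(signif, na.rm = TRUE))
  list(per_freq = per_freq, mean_n = mean(ns), n_rep = n_rep)
}

#' Pattern-separation simulation study
#'
#' Simulates cohorts under a fast-progressing profile, builds the threshold
#' feature array from each fitted ARTA and tests it against the fixed
#' feature array implied by the average profile's noise-free ARTA. Reports
#' how often the chi-square comparison flags a difference.
#'
#' @param n_seeds Number of simulated cohorts (default 200).
#' @param seed Master seed.
#' @param profile Generating profile (default the fast `asp185asn`-like one).
#' @param reference_profile Profile defining the reference array (default
#'   `average`).
#' @param cfg_template Arguments for [cohort_config()] besides `seed`.
#' @param alpha Chi-square significance level.
#' @return List with `fraction_different`, `median_chi2`, `n_seeds`.
#' @export
evaluate_pattern_separation <- function(n_seeds = 200, seed = 1,
                                        profile = progression_profiles()$asp185asn,
                                        reference_profile = progression_profiles()$average,
                                        cfg_template = list(),
                                        alpha = 0.05) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  reference <- build_feature_array(profile_arta(reference_profile))
  freqs <- as.numeric(names(profile$atd_db_per_year))
  different <- logical(n_seeds)
  chi2 <- numeric(n_seeds)
  for (r in seq_len(n_seeds)) {
    cfg <- do.call(cohort_config, c(cfg_template, list(seed = rep_seeds[r])))
    cohort <- simulate_cohort(cfg, profiles = list(profile))
    obs <- arta_observations(cohort)
    fit <- fit_arta(obs, grid = freqs)
    if (!all(fit$atd$fittable)) {
      different[r] <- NA
      chi2[r] <- NA
      next
    }
    arr <- build_feature_array(fit)
    cmp <- compare_feature_arrays(arr, reference, alpha = alpha)
    different[r] <- cmp$different
    chi2[r] <- cmp$chi2
  }
  list(fraction_different = mean(different, na.rm = TRUE),
       median_chi2 = stats::median(chi2, na.rm = TRUE),
       n_seeds = n_seeds)
}
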