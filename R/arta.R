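#' Fit an age-related typical audiogram (ARTA)
#'
#' Performs a cross-sectional ordinary-least-squares regression of binaural
#' hearing threshold on age, separately at every grid frequency, and predicts
#' characteristic thresholds at fixed ages. The per-frequency slope is the
#' annual threshold deterioration (ATD, dB/year); its two-sided t-test on
#' n - 2 degrees of freedom gives the progression significance.
#'
#' Every audiogram is one observation per frequency; repeat visits of the
#' same subject are pooled (cross-sectional convention). Set
#' `average_subjects = TRUE` to collapse repeat visits to one subject-level
#' mean age/threshold first.
#'
#' @param observations Either a list of `binaural_audiogram` objects or a
#'   long data frame with columns `age_years`, `freq_khz`, `threshold_db`
#'   (an optional `subject_id` is used by `average_subjects`).
#' @param grid Frequencies to fit, kHz (default [arta_frequencies()]).
#' @param prediction_ages Ages at which thresholds are predicted (default
#'   decade steps 10--80).
#' @param alpha Significance level for the slope test (default 0.05).
#' @param average_subjects Collapse repeat visits per subject before fitting.
#' @param clip_predictions Clip predictions to the audiometer range
#'   \[-10, 120\] (default `FALSE`; the regression line is the canonical
#'   object, clipping is for plotting).
#'
#' @return Object of class `arta_model`: list with
#'   * `atd`: data frame (freq_khz, slope, intercept, se, p_value, n,
#'     significant, fittable, reason),
#'   * `predicted`: matrix ages x frequencies of predicted dB HL,
#'   * `prediction_ages`, `grid`, `alpha`.
#'   Frequencies with fewer than 3 points or no age spread are flagged
#'   unfittable (`NA` estimates), never silently dropped.
#' @export
#' @examples
#' obs <- data.frame(age_years = seq(10, 80, 10), freq_khz = 1,
#'                   threshold_db = 10 + 0.7 * seq(10, 80, 10))
#' fit <- fit_arta(obs, grid = 1)
#' fit$atd$slope # 0.7
fit_arta <- function(observations, grid = arta_frequencies(),
                     prediction_ages = seq(10, 80, by = 10), alpha = 0.05,
                     average_subjects = FALSE, clip_predictions = FALSE) {
  df <- as_threshold_table(observations)
  stopifnot(is.numeric(prediction_ages), all(is.finite(prediction_ages)),
            alpha > 0, alpha < 1)
  grid <- as.numeric(grid)

  if (average_subjects && "subject_id" %in% names(df)) {
    df <- stats::aggregate(cbind(age_years, threshold_db) ~ subject_id + freq_khz,
                           data = df, FUN = mean, na.action = stats::na.omit)
  }

  rows <- lapply(grid, function(f) {
    sub <- df[df$freq_khz == f & !is.na(df$threshold_db), , drop = FALSE]
    fit_one_frequency(sub$age_years, sub$threshold_db, f, alpha)
  })
  atd <- do.call(rbind, rows)
  rownames(atd) <- NULL

  predicted <- outer(prediction_ages, seq_along(grid), function(a, j) {
    atd$intercept[j] + atd$slope[j] * a
  })
  if (clip_predictions) predicted <- pmin(pmax(predicted, -10), 120)
  dimnames(predicted) <- list(age = as.character(prediction_ages),
                              freq_khz = as.character(grid))

  structure(list(atd = atd, predicted = predicted,
                 prediction_ages = prediction_ages, grid = grid,
                 alpha = alpha),
            class = "arta_model")
}

# OLS of threshold on age at one frequency; explicit degenerate handling:
# zero residual variance cannot reject anything (p = 1) unless the fit is an
# exact nonzero slope (p = 0).
fit_one_frequency <- function(age, y, freq, alpha) {
  n <- length(y)
  unfit <- function(reason) {
    data.frame(freq_khz = freq, slope = NA_real_, intercept = NA_real_,
               se = NA_real_, p_value = NA_real_, n = n,
               significant = FALSE, fittable = FALSE, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (n < 3) return(unfit("fewer than 3 observations"))
  if (length(unique(age)) < 2) return(unfit("no age spread"))

  fit <- stats::lm.fit(cbind(1, age), y)
  intercept <- unname(fit$coefficients[1])
  slope <- unname(fit$coefficients[2])
  rss <- sum(fit$residuals^2)
  sxx <- sum((age - mean(age))^2)
  tss <- sum((y - mean(y))^2)
  tol <- 1e-12 * max(tss, 1)
  if (rss <= tol) {
    se <- 0
    p <- if (abs(slope) <= 1e-12) 1 else 0
  } else {
    se <- sqrt(rss / (n - 2) / sxx)
    tstat <- slope / se
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  data.frame(freq_khz = freq, slope = slope, intercept = intercept,
             se = se, p_value = p, n = n,
             significant = is.finite(p) && p < alpha,
             fittable = TRUE, reason = NA_character_,
             stringsAsFactors = FALSE)
}

# Coerce fit_arta() input to a long threshold table.
as_threshold_table <- function(observations) {
  if (is.data.frame(observations)) {
    need <- c("age_years", "freq_khz", "threshold_db")
    miss <- setdiff(need, names(observations))
    if (length(miss)) {
      stop("missing columns: ", paste(miss, collapse = ", "))
    }
    return(observations)
  }
  if (is.list(observations) &&
      all(vapply(observations, inherits, logical(1), "binaural_audiogram"))) {
    parts <- lapply(observations, function(b) {
      data.frame(subject_id = b$subject_id, age_years = b$age_years,
                 freq_khz = as.numeric(names(b$thresholds)),
                 threshold_db = as.numeric(b$thresholds),
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, parts))
  }
  stop("observations must be a data frame or a list of binaural_audiogram")
}

#' Extract the ATD table from an ARTA model
#' @param model An `arta_model`.
#' @return Data frame with one row per frequency: slope (ATD, dB/year),
#'   intercept, SE, p-value, n, significance flag.
#' @export
atd_table <- function(model) {
  stopifnot(inherits(model, "arta_model"))
  model$atd
}

#' @export
print.arta_model <- function(x, ...) {
  cat(sprintf("<arta_model> %d frequencies, %d prediction ages, alpha = %g\n",
              length(x$grid), length(x$prediction_ages), x$alpha))
  print(x$atd[, c("freq_khz", "slope", "se", "p_value", "n", "significant")],
        digits = 3)
  invisible(x)
}

#' Write an ARTA model to TSV files
#'
#' Writes `arta_matrix.tsv` (rows = ages, columns = frequencies) and
#' `atd_table.tsv`.
#'
#' @param model An `arta_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
export_arta <- function(model, dir) {
  stopifnot(inherits(model, "arta_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_path <- file.path(dir, "arta_matrix.tsv")
  atd_path <- file.path(dir, "atd_table.tsv")
  mat <- data.frame(age = rownames(model$predicted), model$predicted,
                    check.names = FALSE)
  utils::write.table(mat, mat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(model$atd, atd_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mat_path, atd_path))
}

#' Plot an ARTA as a clinical audiogram
#'
#' Threshold against frequency (log axis), one line per prediction age, with
#' the dB axis inverted as on clinical charts.
#'
#' @param model An `arta_model`.
#' @return A ggplot object.
#' @export
plot_arta <- function(model) {
  stopifnot(inherits(model, "arta_model"))
  d <- as.data.frame(as.table(model$predicted), stringsAsFactors = FALSE)
  names(d) <- c("age", "freq_khz", "threshold_db")
  d$freq_khz <- as.numeric(d$freq_khz)
  d$age <- factor(d$age, levels = as.character(model$prediction_ages))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$freq_khz, y = .data$threshold_db,
                                  colour = .data$age, group = .data$age)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10(breaks = model$grid, labels = model$grid) +
    ggplot2::scale_y_reverse(limits = c(120, -10)) +
    ggplot2::labs(x = "Frequency (kHz)", y = "Threshold (dB HL)",
                  colour = "Age (y)") +
    ggplot2::theme_minimal()
}
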