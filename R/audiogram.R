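#' Standard pure-tone test frequencies
#'
#' The clinical air-conduction grid spans 0.125--8 kHz. ARTA construction and
#' ATD estimation use the six-frequency subset for which annual deterioration
#' is conventionally reported.
#'
#' @param freqs_khz Numeric vector of test frequencies in kHz, strictly
#'   increasing and positive.
#' @return A numeric vector of class `frequency_grid`.
#' @export
#' @examples
#' frequency_grid()
#' arta_frequencies()
frequency_grid <- function(freqs_khz = c(0.125, 0.25, 0.5, 1, 2, 4, 8)) {
  if (!is.numeric(freqs_khz) || length(freqs_khz) == 0) {
    stop("freqs_khz must be a non-empty numeric vector")
  }
  if (any(!is.finite(freqs_khz)) || any(freqs_khz <= 0)) {
    stop("frequencies must be finite and positive (kHz)")
  }
  if (is.unsorted(freqs_khz, strictly = TRUE)) {
    stop("frequencies must be strictly increasing")
  }
  structure(as.numeric(freqs_khz), class = "frequency_grid")
}

#' @rdname frequency_grid
#' @export
arta_frequencies <- function() frequency_grid(c(0.25, 0.5, 1, 2, 4, 8))

#' Hearing-loss degree scale
#'
#' Degree bands for pure-tone thresholds in dB HL: normal (<= 20), mild
#' (21--40), moderate (41--70), severe (71--90), profound (> 90). Upper
#' boundaries are inclusive.
#'
#' @return Named numeric vector of inclusive upper boundaries per class
#'   (`profound` is unbounded, stored as `Inf`).
#' @export
degree_scale <- function() {
  c(normal = 20, mild = 40, moderate = 70, severe = 90, profound = Inf)
}

#' Names of the degree classes, worst last
#' @param scale A scale from [degree_scale()].
#' @return Character vector of class labels.
#' @export
degree_classes <- function(scale = degree_scale()) names(scale)

#' Classify thresholds into hearing-loss degree bands
#'
#' @param threshold_db Numeric vector of thresholds in dB HL. Must be finite.
#' @param scale Degree scale from [degree_scale()].
#' @return Ordered factor with levels normal < mild < moderate < severe <
#'   profound.
#' @export
#' @examples
#' classify_degree(c(15, 30, 41, 90, 95))
classify_degree <- function(threshold_db, scale = degree_scale()) {
  if (!is.numeric(threshold_db)) stop("threshold_db must be numeric")
  if (any(!is.finite(threshold_db))) {
    stop("classify_degree: non-finite threshold")
  }
  labs <- names(scale)
  idx <- vapply(threshold_db, function(x) which(x <= scale)[1L], integer(1))
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' Single-ear audiogram
#'
#' One pure-tone air-conduction audiogram: thresholds in dB HL on a frequency
#' grid, measured at one age. Clinical thresholds from the 10-down/5-up
#' search are multiples of 5 dB; `censored` marks frequencies with no
#' response at the audiometer maximum (stored at the maximum output level).
#'
#' @param subject_id,family_id Identifier strings.
#' @param ear `"left"` or `"right"`.
#' @param age_years Age at testing, finite and non-negative.
#' @param thresholds Named numeric vector, names are frequencies in kHz;
#'   `NA` marks a frequency not tested. Values in `[-10, 120]`.
#' @param censored Logical vector parallel to `thresholds` (default all
#'   `FALSE`).
#' @return Object of class `ear_audiogram`.
#' @export
ear_audiogram <- function(subject_id, family_id, ear, age_years, thresholds,
                          censored = NULL) {
  ear <- match.arg(ear, c("left", "right"))
  if (!is.numeric(age_years) || length(age_years) != 1L ||
      !is.finite(age_years) || age_years < 0) {
    stop("age_years must be a single finite non-negative number")
  }
  if (is.null(names(thresholds)) || anyNA(suppressWarnings(as.numeric(names(thresholds))))) {
    stop("thresholds must be named by frequency in kHz")
  }
  bad <- !is.na(thresholds) & (thresholds < -10 | thresholds > 120)
  if (any(bad)) {
    stop("thresholds outside the audiometer range [-10, 120] dB HL: ",
         paste(names(thresholds)[bad], collapse = ", "))
  }
  if (is.null(censored)) censored <- rep(FALSE, length(thresholds))
  structure(
    list(subject_id = as.character(subject_id),
         family_id = as.character(family_id),
         ear = ear, age_years = as.numeric(age_years),
         thresholds = thresholds,
         censored = stats::setNames(as.logical(censored), names(thresholds))),
    class = "ear_audiogram"
  )
}

#' Binaural mean audiogram
#'
#' Per-frequency arithmetic mean of left- and right-ear thresholds. Defined
#' only at frequencies measured in both ears; means of 5-dB-quantized ears
#' may be half-steps and are never re-quantized.
#'
#' @param left,right `ear_audiogram` objects for the same subject and test
#'   session.
#' @param age_tol Maximum allowed difference between the two ears' ages at
#'   testing, in years (default 0: same session).
#' @return Object of class `binaural_audiogram` with fields `subject_id`,
#'   `age_years` (mean of the two ears) and `thresholds`.
#' @export
#' @examples
#' l <- ear_audiogram("s1", "f1", "left", 30, c(`1` = 20))
#' r <- ear_audiogram("s1", "f1", "right", 30, c(`1` = 30))
#' binaural_mean(l, r)$thresholds
binaural_mean <- function(left, right, age_tol = 0) {
  stopifnot(inherits(left, "ear_audiogram"), inherits(right, "ear_audiogram"))
  if (left$subject_id != right$subject_id) {
    stop(sprintf("binaural_mean: subject mismatch ('%s' left vs '%s' right)",
                 left$subject_id, right$subject_id))
  }
  if (abs(left$age_years - right$age_years) > age_tol) {
    stop(sprintf(
      "binaural_mean: age mismatch for subject '%s' (%.2f left vs %.2f right)",
      left$subject_id, left$age_years, right$age_years))
  }
  freqs <- union(names(left$thresholds), names(right$thresholds))
  freqs <- freqs[order(as.numeric(freqs))]
  l <- left$thresholds[freqs]
  r <- right$thresholds[freqs]
  out <- stats::setNames((as.numeric(l) + as.numeric(r)) / 2, freqs)
  structure(
    list(subject_id = left$subject_id,
         family_id = left$family_id,
         age_years = (left$age_years + right$age_years) / 2,
         thresholds = out),
    class = "binaural_audiogram"
  )
}

#' Interaural symmetry rule
#'
#' A subject is called asymmetric when the absolute left-right difference
#' reaches `diff_db` at `min_count` or more of the rule frequencies.
#'
#' @param diff_db Difference threshold in dB (default 15).
#' @param min_count Minimum number of rule frequencies at or above
#'   `diff_db` (default 2).
#' @param freqs_khz Frequencies the rule inspects (default 0.5, 1, 2, 4 kHz).
#' @return A list of class `symmetry_rule`.
#' @export
symmetry_rule <- function(diff_db = 15, min_count = 2,
                          freqs_khz = c(0.5, 1, 2, 4)) {
  stopifnot(diff_db > 0, min_count >= 1, length(freqs_khz) >= 1)
  structure(list(diff_db = diff_db, min_count = min_count,
                 freqs_khz = freqs_khz), class = "symmetry_rule")
}

#' Validate interaural threshold symmetry
#'
#' @param left,right `ear_audiogram` objects.
#' @param rule A [symmetry_rule()].
#' @return List with `symmetric` (logical), `per_freq_diff` (named |L-R|),
#'   and `flagged_freqs` (rule frequencies at or above the difference
#'   threshold).
#' @export
check_symmetry <- function(left, right, rule = symmetry_rule()) {
  stopifnot(inherits(left, "ear_audiogram"), inherits(right, "ear_audiogram"))
  freqs <- intersect(names(left$thresholds), names(right$thresholds))
  l <- left$thresholds[freqs]
  r <- right$thresholds[freqs]
  keep <- !is.na(l) & !is.na(r)
  if (sum(keep) < 3) {
    stop("check_symmetry: fewer than 3 overlapping measured frequencies")
  }
  d <- abs(as.numeric(l[keep]) - as.numeric(r[keep]))
  names(d) <- freqs[keep]
  rf <- as.character(rule$freqs_khz)
  hits <- names(d)[names(d) %in% rf & d >= rule$diff_db]
  list(symmetric = length(hits) < rule$min_count,
       per_freq_diff = d,
       flagged_freqs = as.numeric(hits))
}

#' @export
print.ear_audiogram <- function(x, ...) {
  cat(sprintf("<ear_audiogram> %s (%s ear), family %s, age %.1f y\n",
              x$subject_id, x$ear, x$family_id, x$age_years))
  print(x$thresholds)
  invisible(x)
}

#' @export
print.binaural_audiogram <- function(x, ...) {
  cat(sprintf("<binaural_audiogram> %s, age %.1f y\n",
              x$subject_id, x$age_years))
  print(x$thresholds)
  invisible(x)
}
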