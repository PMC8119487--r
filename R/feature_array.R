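#' Frequency-band map
#'
#' Assigns each ARTA frequency to a low (lf), mid (mf) or high (hf) band.
#' The default splits the six ATD frequencies two per band.
#'
#' @param map Named character vector, names are frequencies in kHz, values
#'   band labels.
#' @return Object of class `frequency_bands`.
#' @export
frequency_bands <- function(map = c(`0.25` = "lf", `0.5` = "lf",
                                    `1` = "mf", `2` = "mf",
                                    `4` = "hf", `8` = "hf")) {
  if (is.null(names(map)) || any(names(map) == "")) {
    stop("band map must be named by frequency (kHz)")
  }
  structure(map, class = "frequency_bands")
}

#' Band labels in low-to-high order
#' @param bands A [frequency_bands()] map.
#' @return Character vector of band labels, first occurrence order.
#' @export
band_levels <- function(bands = frequency_bands()) unique(unname(bands))

#' Look up the band of a frequency
#'
#' @param freq_khz Frequency (kHz), must be present in the band map.
#' @param bands A [frequency_bands()] map.
#' @return Band label.
#' @export
#' @examples
#' assign_band(0.25) # "lf"
#' assign_band(8)    # "hf"
assign_band <- function(freq_khz, bands = frequency_bands()) {
  key <- as.character(freq_khz)
  hit <- match(key, names(bands))
  if (anyNA(hit)) {
    stop("assign_band: frequency not in band map: ",
         paste(key[is.na(hit)], collapse = ", "))
  }
  unname(unclass(bands)[hit])
}

#' Construct a threshold feature array from counts
#'
#' @param counts Integer matrix, rows = degree classes, columns = bands.
#' @return Object of class `feature_array` with `counts` and `total`.
#' @export
feature_array <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("feature array counts must be non-negative integers")
  }
  structure(list(counts = counts, total = sum(counts)),
            class = "feature_array")
}

#' Tally ARTA grid points into a threshold feature array
#'
#' Each predicted (age, frequency) point of the ARTA grid is classified by
#' hearing-loss degree and tallied into its (degree class, frequency band)
#' cell. The total count equals the grid size (ages x frequencies).
#'
#' @param model An `arta_model` with predictions at all grid frequencies.
#' @param scale Degree scale (default [degree_scale()]).
#' @param bands Band map (default [frequency_bands()]).
#' @param include_normal Keep the "normal" row (default `TRUE`); when
#'   `FALSE` points below the mild band are dropped from the array.
#' @return A `feature_array`.
#' @export
build_feature_array <- function(model, scale = degree_scale(),
                                bands = frequency_bands(),
                                include_normal = TRUE) {
  stopifnot(inherits(model, "arta_model"))
  pred <- model$predicted
  if (anyNA(pred)) {
    stop("build_feature_array: model has unfittable frequencies (NA predictions)")
  }
  freqs <- as.numeric(colnames(pred))
  band_of <- assign_band(freqs, bands)
  degs <- degree_classes(scale)
  bl <- band_levels(bands)

  counts <- matrix(0L, nrow = length(degs), ncol = length(bl),
                   dimnames = list(degree = degs, band = bl))
  for (j in seq_along(freqs)) {
    cls <- classify_degree(pred[, j], scale)
    tab <- table(cls)
    counts[names(tab), band_of[j]] <- counts[names(tab), band_of[j]] +
      as.integer(tab)
  }
  if (!include_normal) counts <- counts[rownames(counts) != "normal", , drop = FALSE]
  feature_array(counts)
}

#' Compare two threshold feature arrays by chi-square goodness of fit
#'
#' The reference array defines expected proportions; expected counts are the
#' reference proportions scaled to the observed total. Cells with expected
#' count below `pool_threshold` are pooled into a single remainder cell
#' before the test (classical validity guard); if the remainder itself still
#' falls below the threshold (e.g. the reference puts zero mass there) it is
#' merged into the retained cell with the smallest expectation, so the
#' statistic stays finite. The statistic is sum((O - E)^2 / E) with
#' df = retained cells - 1; the reference is treated as a fixed external
#' distribution, not estimated from the observed data.
#'
#' @param observed,reference `feature_array` objects with identical cell
#'   layout.
#' @param alpha Significance level (default 0.05).
#' @param pool_threshold Pool cells with expected count below this value
#'   (default 1).
#' @return List with `chi2`, `df`, `p`, `different` (p < alpha), and
#'   `n_pooled` (cells merged into the remainder).
#' @export
#' @examples
#' a <- feature_array(matrix(c(10, 0), 1))
#' b <- feature_array(matrix(c(5, 5), 1))
#' compare_feature_arrays(a, b) # chi2 = 10, df = 1
compare_feature_arrays <- function(observed, reference, alpha = 0.05,
                                   pool_threshold = 1) {
  stopifnot(inherits(observed, "feature_array"),
            inherits(reference, "feature_array"))
  if (!identical(dim(observed$counts), dim(reference$counts))) {
    stop("observed and reference arrays must share the same cell layout")
  }
  o <- as.vector(observed$counts)
  r <- as.vector(reference$counts)
  n <- sum(o)
  if (n == 0) stop("observed array has total count 0")
  if (sum(r) == 0) stop("reference array has total count 0")
  e <- r / sum(r) * n

  pool <- e < pool_threshold
  if (all(pool)) {
    stop("all reference mass falls below the pooling threshold; test undefined")
  }
  if (any(pool)) {
    o_rem <- sum(o[pool]); e_rem <- sum(e[pool])
    o <- o[!pool]; e <- e[!pool]
    if (e_rem >= pool_threshold) {
      o <- c(o, o_rem); e <- c(e, e_rem)
    } else {
      # remainder still under-supported: fold it into the weakest retained
      # cell so every expected count stays valid and the statistic finite
      j <- which.min(e)
      o[j] <- o[j] + o_rem
      e[j] <- e[j] + e_rem
    }
  }
  if (length(o) < 2) stop("fewer than 2 cells retained; test undefined")
  chi2 <- sum((o - e)^2 / e)
  df <- length(o) - 1L
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p, different = p < alpha,
       n_pooled = sum(pool))
}

#' @export
print.feature_array <- function(x, ...) {
  cat(sprintf("<feature_array> total = %d points\n", x$total))
  print(x$counts)
  invisible(x)
}

#' Write a feature array as CSV (rows = degree classes, columns = bands)
#' @param x A `feature_array`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_array <- function(x, path) {
  stopifnot(inherits(x, "feature_array"))
  utils::write.csv(as.data.frame(x$counts), path, row.names = TRUE)
  invisible(path)
}

#' Heatmap of a threshold feature array
#' @param x A `feature_array`.
#' @return A ggplot object.
#' @export
plot_feature_array <- function(x) {
  stopifnot(inherits(x, "feature_array"))
  d <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  names(d) <- c("degree", "band", "count")
  d$degree <- factor(d$degree, levels = rev(rownames(x$counts)))
  d$band <- factor(d$band, levels = colnames(x$counts))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$band, y = .data$degree,
                                  fill = .data$count)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Frequency band", y = "HL degree", fill = "Points") +
    ggplot2::theme_minimal()
}
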