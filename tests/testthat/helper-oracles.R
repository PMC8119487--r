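# Independent closed-form OLS oracle: explicit sums of squares, t tail on
# n - 2 df. Kept free of any package code paths.
ols_oracle <- function(age, y) {
  n <- length(y)
  abar <- mean(age)
  ybar <- mean(y)
  sxx <- sum((age - abar)^2)
  sxy <- sum((age - abar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * abar
  rss <- sum((y - intercept - slope * age)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- 2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, se = se, p = p)
}

# Brute-force co-segregation count: materialise every parent->offspring edge,
# then filter/classify row by row. Independent of count_segregations().
segregation_oracle <- function(ped, obs, proband) {
  ind <- ped$individuals
  geno <- setNames(rep("untyped", nrow(ind)), ind$id)
  geno[names(obs$genotypes)] <- obs$genotypes
  edges <- rbind(
    data.frame(parent = ind$father, child = ind$id),
    data.frame(parent = ind$mother, child = ind$id))
  edges <- edges[!is.na(edges$parent), ]
  n_inf <- 0L; n_con <- 0L; disc <- character(0)
  for (i in seq_len(nrow(edges))) {
    p <- edges$parent[i]; ch <- edges$child[i]
    if (ch == proband) next
    if (geno[p] != "het") next
    if (!geno[ch] %in% c("het", "ref")) next
    aff <- ind$affected[ind$id == ch]
    if (!aff %in% c("yes", "no")) next
    n_inf <- n_inf + 1L
    if ((geno[ch] == "het" && aff == "yes") ||
        (geno[ch] == "ref" && aff == "no")) {
      n_con <- n_con + 1L
    } else {
      disc <- c(disc, ch)
    }
  }
  list(n_informative = n_inf, n_concordant = n_con,
       discordants = unique(disc))
}

# Minimal arta_model with prescribed predictions, for feature-array tests.
make_arta_model <- function(predicted, ages, freqs) {
  dimnames(predicted) <- list(age = as.character(ages),
                              freq_khz = as.character(freqs))
  structure(list(
    atd = data.frame(freq_khz = freqs, slope = NA_real_,
                     intercept = NA_real_, se = NA_real_,
                     p_value = NA_real_, n = nrow(predicted),
                     significant = NA, fittable = TRUE,
                     reason = NA_character_),
    predicted = predicted, prediction_ages = ages, grid = freqs,
    alpha = 0.05), class = "arta_model")
}

random_ear <- function(subject = "s", ear = "left", age = 40,
                       freqs = c(0.25, 0.5, 1, 2, 4, 8)) {
  thr <- 5 * sample(-2:24, length(freqs), replace = TRUE)
  ear_audiogram(subject, "f", ear, age, setNames(thr, freqs))
}

fixture_path <- function(...) system.file("extdata", ..., package = "artakit")
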