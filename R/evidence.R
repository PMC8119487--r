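#' Population frequency record for a variant
#'
#' @param variant_id Variant label.
#' @param af_by_db Named numeric vector of allele frequencies by database;
#'   `NA` means the variant is absent from that database.
#' @return Object of class `population_frequency_record`.
#' @export
population_frequency_record <- function(variant_id, af_by_db) {
  if (length(af_by_db) == 0 || is.null(names(af_by_db))) {
    stop("af_by_db must be a non-empty named numeric vector")
  }
  ok <- is.na(af_by_db) | (af_by_db >= 0 & af_by_db <= 1)
  if (!all(ok)) stop("allele frequencies must lie in [0, 1]")
  structure(list(variant_id = as.character(variant_id),
                 af_by_db = af_by_db),
            class = "population_frequency_record")
}

#' Evaluate the PM2 rarity criterion
#'
#' PM2 is met when the variant is absent from, or very rare in, every queried
#' population database.
#'
#' @param rec A [population_frequency_record()].
#' @param max_af Maximum allele frequency compatible with rarity
#'   (default 2e-5).
#' @return List with `met` (logical) and `rationale` (string).
#' @export
#' @examples
#' rec <- population_frequency_record("c.553G>A",
#'          c(gnomAD = 0, UK10K = 0, EVS = 0))
#' evaluate_pm2(rec)$met # TRUE
evaluate_pm2 <- function(rec, max_af = 2e-5) {
  stopifnot(inherits(rec, "population_frequency_record"))
  af <- rec$af_by_db
  rare <- is.na(af) | af <= max_af
  met <- all(rare)
  desc <- paste(sprintf("%s=%s", names(af),
                        ifelse(is.na(af), "absent", format(af))),
                collapse = ", ")
  rationale <- if (met) {
    sprintf("absent or AF <= %g in all databases (%s)", max_af, desc)
  } else {
    sprintf("AF > %g in %s (%s)", max_af,
            paste(names(af)[!rare], collapse = ", "), desc)
  }
  list(met = met, rationale = rationale)
}

#' Count informative co-segregation meioses
#'
#' An informative meiosis is a parent-to-offspring transmission in which the
#' parent is a genotyped heterozygous carrier and the offspring is genotyped
#' with known affection status. The transmission that produced the proband is
#' excluded (ascertainment). A transmission is concordant when the offspring
#' is an affected carrier or an unaffected non-carrier; all other informative
#' transmissions are discordant.
#'
#' Under `penetrance_mode = "age_dependent"`, unaffected carriers younger
#' than `onset_age` are excluded from the informative count (their phenotype
#' cannot yet be assessed).
#'
#' @param ped A [pedigree()].
#' @param obs A [variant_observation()]; the proband must be genotyped `het`.
#' @param penetrance_mode `"full"` (default) or `"age_dependent"`.
#' @param onset_age Onset age in years, required for `age_dependent`.
#' @param infer_obligate Infer `het` for untyped individuals that have both a
#'   genotyped het ancestor and a genotyped het descendant (default `FALSE`).
#' @return List with `n_informative`, `n_concordant` and `discordants`
#'   (character vector of offspring ids).
#' @export
count_segregations <- function(ped, obs,
                               penetrance_mode = c("full", "age_dependent"),
                               onset_age = NULL, infer_obligate = FALSE) {
  stopifnot(inherits(ped, "pedigree"), inherits(obs, "variant_observation"))
  penetrance_mode <- match.arg(penetrance_mode)
  if (penetrance_mode == "age_dependent" && is.null(onset_age)) {
    stop("onset_age is required under age_dependent penetrance")
  }
  ind <- ped$individuals
  unknown <- setdiff(names(obs$genotypes), ind$id)
  if (length(unknown)) {
    stop("genotyped individual(s) not in pedigree: ",
         paste(unknown, collapse = ", "))
  }
  geno <- stats::setNames(rep("untyped", nrow(ind)), ind$id)
  geno[names(obs$genotypes)] <- obs$genotypes
  proband <- ped$proband_id
  if (is.null(proband)) stop("pedigree has no proband")
  if (geno[proband] != "het") {
    stop("proband '", proband, "' is not a genotyped het carrier")
  }
  if (infer_obligate) geno <- infer_obligate_carriers(ind, geno)

  ages <- if ("age_years" %in% names(ind)) {
    stats::setNames(ind$age_years, ind$id)
  } else {
    stats::setNames(rep(NA_real_, nrow(ind)), ind$id)
  }
  aff <- stats::setNames(ind$affected, ind$id)

  n_inf <- 0L
  n_con <- 0L
  discordants <- character(0)
  for (k in seq_len(nrow(ind))) {
    child <- ind$id[k]
    if (child == proband) next
    if (!geno[child] %in% c("het", "ref")) next
    if (!aff[child] %in% c("yes", "no")) next
    if (penetrance_mode == "age_dependent" &&
        geno[child] == "het" && aff[child] == "no" &&
        !is.na(ages[child]) && ages[child] < onset_age) next
    for (parent in c(ind$father[k], ind$mother[k])) {
      if (is.na(parent) || geno[parent] != "het") next
      n_inf <- n_inf + 1L
      concordant <- (geno[child] == "het" && aff[child] == "yes") ||
        (geno[child] == "ref" && aff[child] == "no")
      if (concordant) {
        n_con <- n_con + 1L
      } else {
        discordants <- c(discordants, child)
      }
    }
  }
  list(n_informative = n_inf, n_concordant = n_con,
       discordants = unique(discordants))
}

# Mark untyped individuals het when a genotyped het ancestor and a genotyped
# het descendant both exist (obligate transmitting carriers).
infer_obligate_carriers <- function(ind, geno) {
  parents_of <- function(i) {
    row <- ind[ind$id == i, ]
    c(row$father, row$mother)[!is.na(c(row$father, row$mother))]
  }
  ancestors <- function(i) {
    out <- character(0)
    queue <- parents_of(i)
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      if (p %in% out) next
      out <- c(out, p)
      queue <- c(queue, parents_of(p))
    }
    out
  }
  hets <- names(geno)[geno == "het"]
  anc_list <- lapply(stats::setNames(ind$id, ind$id), ancestors)
  for (i in ind$id[geno == "untyped"]) {
    has_het_anc <- any(hets %in% anc_list[[i]])
    has_het_desc <- any(vapply(hets, function(h) i %in% anc_list[[h]],
                               logical(1)))
    if (has_het_anc && has_het_desc) geno[i] <- "het"
  }
  geno
}

#' Grade the PP1 co-segregation criterion
#'
#' Strength scales with the number of concordant informative meioses;
#' defaults follow the common 3/5/7 tier heuristic. Any discordant meiosis
#' under full penetrance caps the grade at `"none"`.
#'
#' @param n_concordant Non-negative count of concordant meioses.
#' @param discordants_empty `TRUE` when no discordant meioses were observed.
#' @param tiers Named vector with minimum counts for `supporting`,
#'   `moderate` and `strong`.
#' @return One of `"none"`, `"supporting"`, `"moderate"`, `"strong"`.
#' @export
grade_pp1 <- function(n_concordant, discordants_empty = TRUE,
                      tiers = c(supporting = 3, moderate = 5, strong = 7)) {
  if (!is.numeric(n_concordant) || n_concordant < 0) {
    stop("n_concordant must be non-negative")
  }
  stopifnot(all(c("supporting", "moderate", "strong") %in% names(tiers)))
  if (!discordants_empty) return("none")
  if (n_concordant >= tiers[["strong"]]) return("strong")
  if (n_concordant >= tiers[["moderate"]]) return("moderate")
  if (n_concordant >= tiers[["supporting"]]) return("supporting")
  "none"
}

# ACMG criterion vocabulary and default strengths by code family.
acmg_default_strength <- function(code) {
  if (grepl("^PVS", code)) return("very_strong")
  if (grepl("^PS", code)) return("strong")
  if (grepl("^PM", code)) return("moderate")
  if (grepl("^PP", code)) return("supporting")
  if (grepl("^BA", code)) return("stand_alone")
  if (grepl("^BS", code)) return("strong")
  if (grepl("^BP", code)) return("supporting")
  stop("unknown ACMG criterion code: ", code)
}

#' Assemble an ACMG evidence set
#'
#' @param codes Character vector of criterion codes (PVS1, PS1-4, PM1-6,
#'   PP1-5, BA1, BS1-4, BP1-7).
#' @param strengths Optional character vector of applied strengths
#'   (`supporting`, `moderate`, `strong`, `very_strong`, `stand_alone`);
#'   defaults follow the code family. Strength modification (e.g. PP1 applied
#'   as strong) is expressed here.
#' @return Data frame of class `evidence_set` with columns `code`, `strength`
#'   and `side`.
#' @export
#' @examples
#' acmg_evidence(c("PM2", "PP1"), c(NA, "strong"))
acmg_evidence <- function(codes, strengths = NULL) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("duplicated criterion codes")
  defaults <- vapply(codes, acmg_default_strength, character(1))
  if (is.null(strengths)) {
    strengths <- defaults
  } else {
    strengths <- ifelse(is.na(strengths), defaults, strengths)
  }
  valid <- c("supporting", "moderate", "strong", "very_strong", "stand_alone")
  if (length(codes) && !all(strengths %in% valid)) {
    stop("strengths must be one of: ", paste(valid, collapse = ", "))
  }
  side <- ifelse(grepl("^(PVS|PS|PM|PP)", codes), "pathogenic", "benign")
  structure(data.frame(code = codes, strength = strengths, side = side,
                       stringsAsFactors = FALSE),
            class = c("evidence_set", "data.frame"))
}

#' Combine ACMG evidence into a classification
#'
#' Deterministic application of the standard ACMG/AMP combining rules
#' (Richards et al. 2015 rule table). Combinations reached by neither the
#' pathogenic nor the benign rules, and conflicting combinations, yield
#' `"VUS"`.
#'
#' @param evidence An [acmg_evidence()] set.
#' @return One of `"pathogenic"`, `"likely_pathogenic"`, `"VUS"`,
#'   `"likely_benign"`, `"benign"`.
#' @export
#' @examples
#' combine_acmg(acmg_evidence(c("PM2", "PP1"), c(NA, "strong")))
combine_acmg <- function(evidence) {
  stopifnot(inherits(evidence, "evidence_set"))
  p <- evidence[evidence$side == "pathogenic", ]
  b <- evidence[evidence$side == "benign", ]
  pvs <- sum(p$strength == "very_strong")
  ps <- sum(p$strength == "strong")
  pm <- sum(p$strength == "moderate")
  pp <- sum(p$strength == "supporting")
  ba <- sum(b$strength == "stand_alone")
  bs <- sum(b$strength == "strong")
  bp <- sum(b$strength == "supporting")

  pathogenic <-
    (pvs >= 1 && (ps >= 1 || pm >= 2 || (pm == 1 && pp >= 1) || pp >= 2)) ||
    ps >= 2 ||
    (ps == 1 && (pm >= 3 || (pm == 2 && pp >= 2) || (pm == 1 && pp >= 4)))
  likely_pathogenic <-
    (pvs >= 1 && pm >= 1) ||
    (ps == 1 && pm >= 1) ||
    (ps == 1 && pp >= 2) ||
    pm >= 3 ||
    (pm == 2 && pp >= 2) ||
    (pm == 1 && pp >= 4)
  benign <- ba >= 1 || bs >= 2
  likely_benign <- (bs == 1 && bp >= 1) || bp >= 2

  path_class <- if (pathogenic) "pathogenic" else if (likely_pathogenic) "likely_pathogenic" else NA
  ben_class <- if (benign) "benign" else if (likely_benign) "likely_benign" else NA
  if (!is.na(path_class) && !is.na(ben_class)) return("VUS")
  if (!is.na(path_class)) return(path_class)
  if (!is.na(ben_class)) return(ben_class)
  "VUS"
}

#' Classify a variant from family and population evidence
#'
#' Runs the full evidence chain: PM2 from population frequencies, PP1 from
#' pedigree co-segregation (graded by informative meioses), then the ACMG
#' combining rules.
#'
#' @param ped A [pedigree()] with a proband.
#' @param obs A [variant_observation()].
#' @param freq_record A [population_frequency_record()].
#' @param max_af PM2 rarity cutoff (default 2e-5).
#' @param tiers PP1 tier table (see [grade_pp1()]).
#' @param penetrance_mode,onset_age Passed to [count_segregations()].
#' @return List of class `variant_classification` with the variant id, the
#'   evidence set, per-criterion rationale and the final class.
#' @export
classify_variant <- function(ped, obs, freq_record, max_af = 2e-5,
                             tiers = c(supporting = 3, moderate = 5, strong = 7),
                             penetrance_mode = "full", onset_age = NULL) {
  pm2 <- evaluate_pm2(freq_record, max_af = max_af)
  seg <- count_segregations(ped, obs, penetrance_mode = penetrance_mode,
                            onset_age = onset_age)
  pp1_strength <- grade_pp1(seg$n_concordant,
                            discordants_empty = length(seg$discordants) == 0,
                            tiers = tiers)
  codes <- character(0)
  strengths <- character(0)
  rationale <- list()
  if (pm2$met) {
    codes <- c(codes, "PM2")
    strengths <- c(strengths, NA)
    rationale$PM2 <- pm2$rationale
  }
  if (pp1_strength != "none") {
    codes <- c(codes, "PP1")
    strengths <- c(strengths, pp1_strength)
    rationale$PP1 <- sprintf(
      "%d/%d concordant informative meioses (proband excluded) -> %s",
      seg$n_concordant, seg$n_informative, pp1_strength)
  }
  ev <- acmg_evidence(codes, strengths)
  structure(list(variant_id = obs$variant_id,
                 family_id = ped$family_id,
                 evidence = ev,
                 segregation = seg,
                 rationale = rationale,
                 class = combine_acmg(ev)),
            class = "variant_classification")
}

#' @export
print.variant_classification <- function(x, ...) {
  cat(sprintf("<variant_classification> %s (family %s): %s\n",
              x$variant_id, x$family_id, x$class))
  if (nrow(x$evidence)) {
    cat("  criteria:",
        paste(sprintf("%s(%s)", x$evidence$code, x$evidence$strength),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a variant evidence report as JSON
#' @param x A `variant_classification`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_evidence_report <- function(x, path) {
  stopifnot(inherits(x, "variant_classification"))
  out <- list(variant = x$variant_id,
              family = x$family_id,
              criteria = x$evidence[, c("code", "strength")],
              segregation = x$segregation[c("n_informative", "n_concordant")],
              rationale = x$rationale,
              class = x$class)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Cohort screening prevalence
#'
#' Fraction of screened families in which a causative variant was found.
#'
#' @param n_positive Families with a causative variant.
#' @param n_screened Families screened.
#' @return List with `fraction`, `percent` and `percent_rounded`.
#' @export
#' @examples
#' cohort_prevalence(4, 102) # 3.92%, rounds to 4%
cohort_prevalence <- function(n_positive, n_screened) {
  stopifnot(n_positive >= 0, n_screened > 0, n_positive <= n_screened)
  frac <- n_positive / n_screened
  list(fraction = frac, percent = 100 * frac,
       percent_rounded = round(100 * frac))
}
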