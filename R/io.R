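#' Read a long-format audiogram table
#'
#' Expected CSV columns: `subject_id, family_id, ear, age_years, freq_khz,
#' threshold_db[, censored]`. Missing thresholds are empty cells. Invalid
#' rows (negative or non-finite age, ear not left/right, threshold outside
#' the audiometer range) are rejected and reported with their line numbers;
#' thresholds that are not multiples of 5 dB raise a warning but are kept,
#' since real data may deviate from the 5-dB search resolution.
#'
#' @param path CSV file.
#' @return Data frame of class `audiogram_table` with the validated rows; the
#'   rejected rows (with a `reason` column) are attached as attribute
#'   `"rejected"`.
#' @export
read_audiograms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty audiogram file: ", path)
  need <- c("subject_id", "family_id", "ear", "age_years", "freq_khz",
            "threshold_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (!"censored" %in% names(df)) df$censored <- FALSE
  df$censored[is.na(df$censored)] <- FALSE

  reason <- rep(NA_character_, nrow(df))
  bad_age <- !is.finite(df$age_years) | df$age_years < 0
  reason[bad_age] <- "invalid age"
  bad_ear <- !df$ear %in% c("left", "right")
  reason[is.na(reason) & bad_ear] <- "ear must be left/right"
  bad_freq <- !is.finite(df$freq_khz) | df$freq_khz <= 0
  reason[is.na(reason) & bad_freq] <- "invalid frequency"
  out_of_range <- !is.na(df$threshold_db) &
    (df$threshold_db < -10 | df$threshold_db > 120)
  reason[is.na(reason) & out_of_range] <- "threshold outside [-10, 120]"

  rejected <- df[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) {
    rejected$line <- which(!is.na(reason)) + 1L # header is line 1
    rejected$reason <- reason[!is.na(reason)]
    message(sprintf("read_audiograms: rejected %d row(s): %s",
                    nrow(rejected),
                    paste(sprintf("line %d (%s)", rejected$line,
                                  rejected$reason), collapse = "; ")))
  }
  kept <- df[is.na(reason), , drop = FALSE]
  off_grid <- !is.na(kept$threshold_db) & kept$threshold_db %% 5 != 0
  if (any(off_grid)) {
    warning(sprintf("%d threshold(s) are not multiples of 5 dB; kept",
                    sum(off_grid)))
  }
  rownames(kept) <- NULL
  class(kept) <- c("audiogram_table", "data.frame")
  if (nrow(rejected)) attr(kept, "rejected") <- rejected
  kept
}

#' Write a long-format audiogram table
#' @param df Data frame with the audiogram-table columns.
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_audiograms <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Split an audiogram table into ear_audiogram objects
#' @param tbl An `audiogram_table` (or compatible data frame).
#' @return List of [ear_audiogram()] objects, one per (subject, ear, age).
#' @export
ear_audiograms <- function(tbl) {
  key <- interaction(tbl$subject_id, tbl$ear, tbl$age_years, drop = TRUE)
  lapply(split(seq_len(nrow(tbl)), key), function(idx) {
    sub <- tbl[idx, ]
    ear_audiogram(sub$subject_id[1], sub$family_id[1], sub$ear[1],
                  sub$age_years[1],
                  stats::setNames(sub$threshold_db, sub$freq_khz),
                  censored = sub$censored)
  })
}

#' Binaural mean table from an ear-level audiogram table
#'
#' @param tbl An `audiogram_table`.
#' @param include_single_ear Admit frequencies measured in one ear only
#'   (default `FALSE`: both ears required).
#' @return Data frame subject_id, family_id, age_years, freq_khz,
#'   threshold_db suitable for [fit_arta()].
#' @export
binaural_table <- function(tbl, include_single_ear = FALSE) {
  df <- as.data.frame(tbl)
  df <- df[!is.na(df$threshold_db), , drop = FALSE]
  agg <- stats::aggregate(
    threshold_db ~ subject_id + family_id + age_years + freq_khz,
    data = df, FUN = mean)
  cnt <- stats::aggregate(
    threshold_db ~ subject_id + family_id + age_years + freq_khz,
    data = df, FUN = length)
  if (!include_single_ear) agg <- agg[cnt$threshold_db >= 2, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Read a pedigree and its genotype sidecar
#'
#' The PED file is the 6-column dialect (family, individual, father, mother,
#' sex, phenotype), whitespace-delimited, no header; `0` means
#' founder/unknown parent, sex 1 = male / 2 = female / 0 = unknown, phenotype
#' 2 = affected / 1 = unaffected / 0 or -9 = unknown. The genotype CSV has
#' columns `individual_id, genotype[, age_years]` with genotype
#' het/ref/untyped; a `variant_id` column (constant) names the variant.
#'
#' @param ped_path PED file.
#' @param genotype_path Genotype CSV.
#' @param proband_id Optional proband (defaults to a `proband` column flag in
#'   the genotype CSV if present).
#' @return List with `pedigree` and `observation`.
#' @export
read_pedigree <- function(ped_path, genotype_path, proband_id = NULL) {
  ped <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "phenotype"))
  if (nrow(ped) == 0) stop("empty PED file: ", ped_path)
  sex <- c("unknown", "male", "female")[match(ped$sex, c(0, 1, 2))]
  if (anyNA(sex)) stop("PED sex codes must be 0/1/2")
  affected <- rep("unknown", nrow(ped))
  affected[ped$phenotype == 2] <- "yes"
  affected[ped$phenotype == 1] <- "no"
  ind <- data.frame(id = as.character(ped$id),
                    father = ifelse(ped$father == "0", NA,
                                    as.character(ped$father)),
                    mother = ifelse(ped$mother == "0", NA,
                                    as.character(ped$mother)),
                    sex = sex, affected = affected,
                    stringsAsFactors = FALSE)

  gt <- utils::read.csv(genotype_path, stringsAsFactors = FALSE)
  need <- c("individual_id", "genotype")
  miss <- setdiff(need, names(gt))
  if (length(miss)) stop("missing columns in ", genotype_path, ": ",
                         paste(miss, collapse = ", "))
  unknown <- setdiff(gt$individual_id, ind$id)
  if (length(unknown)) {
    stop("genotype rows for unknown individual(s): ",
         paste(unknown, collapse = ", "))
  }
  if ("age_years" %in% names(gt)) {
    ind$age_years <- gt$age_years[match(ind$id, gt$individual_id)]
  }
  if (is.null(proband_id) && "proband" %in% names(gt)) {
    flag <- gt$individual_id[gt$proband %in% c(1, TRUE, "TRUE", "yes")]
    if (length(flag) == 1) proband_id <- flag
  }
  variant_id <- if ("variant_id" %in% names(gt)) gt$variant_id[1] else "variant"
  ped_obj <- pedigree(ind, proband_id = proband_id,
                      family_id = as.character(ped$family[1]))
  obs <- variant_observation(
    variant_id, stats::setNames(gt$genotype, gt$individual_id))
  list(pedigree = ped_obj, observation = obs)
}

#' Write a pedigree and genotypes to PED + CSV
#'
#' @param ped A [pedigree()].
#' @param obs A [variant_observation()].
#' @param ped_path,genotype_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_pedigree <- function(ped, obs, ped_path, genotype_path) {
  stopifnot(inherits(ped, "pedigree"), inherits(obs, "variant_observation"))
  ind <- ped$individuals
  out <- data.frame(
    family = ped$family_id,
    id = ind$id,
    father = ifelse(is.na(ind$father), "0", ind$father),
    mother = ifelse(is.na(ind$mother), "0", ind$mother),
    sex = match(ind$sex, c("unknown", "male", "female")) - 1L,
    phenotype = c(yes = 2L, no = 1L, unknown = 0L)[ind$affected])
  utils::write.table(out, ped_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gt <- data.frame(individual_id = names(obs$genotypes),
                   genotype = as.character(obs$genotypes),
                   variant_id = obs$variant_id,
                   proband = as.integer(names(obs$genotypes) %in%
                                          ped$proband_id))
  if ("age_years" %in% names(ind)) {
    gt$age_years <- ind$age_years[match(gt$individual_id, ind$id)]
  }
  utils::write.csv(gt, genotype_path, row.names = FALSE)
  invisible(c(ped_path, genotype_path))
}

#' Read a variant population-frequency table
#'
#' CSV with a `variant_id` column; remaining numeric columns are database
#' allele frequencies (empty cell = absent from that database).
#'
#' @param path CSV file.
#' @return Named list of [population_frequency_record()] objects.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"variant_id" %in% names(df)) stop("missing variant_id column in ", path)
  dbs <- setdiff(names(df), c("variant_id", "family", "protein"))
  recs <- lapply(seq_len(nrow(df)), function(i) {
    af <- stats::setNames(as.numeric(df[i, dbs]), dbs)
    population_frequency_record(df$variant_id[i], af)
  })
  stats::setNames(recs, df$variant_id)
}

#' Write the cohort dataset to disk
#'
#' Writes `audiograms.csv`, one `<family>.ped` + `<family>_genotypes.csv`
#' pair per family, and `truth.json` with the ground-truth slopes, onsets and
#' carrier status.
#'
#' @param cohort An `adhl_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "adhl_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_audiograms(cohort$audiograms, file.path(dir, "audiograms.csv"))
  for (fam in names(cohort$pedigrees)) {
    write_pedigree(cohort$pedigrees[[fam]], cohort$observations[[fam]],
                   file.path(dir, paste0(fam, ".ped")),
                   file.path(dir, paste0(fam, "_genotypes.csv")))
  }
  truth <- lapply(cohort$truth, function(t) {
    list(profile = t$profile, onset_age_years = t$onset_age_years,
         atd_db_per_year = as.list(t$atd_db_per_year),
         baseline_db = as.list(t$baseline_db),
         carriers = as.list(t$carriers))
  })
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort dataset written by [write_cohort()]
#'
#' @param dir Directory produced by [write_cohort()].
#' @return List with `audiograms`, `pedigrees`, `observations`, `truth`.
#' @export
read_cohort <- function(dir) {
  aud <- read_audiograms(file.path(dir, "audiograms.csv"))
  ped_files <- sort(list.files(dir, pattern = "\\.ped$", full.names = TRUE))
  fams <- sub("\\.ped$", "", basename(ped_files))
  peds <- list(); obss <- list()
  for (i in seq_along(ped_files)) {
    res <- read_pedigree(ped_files[i],
                         file.path(dir, paste0(fams[i], "_genotypes.csv")))
    peds[[fams[i]]] <- res$pedigree
    obss[[fams[i]]] <- res$observation
  }
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(audiograms = aud, pedigrees = peds, observations = obss,
       truth = truth)
}
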