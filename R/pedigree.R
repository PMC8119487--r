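#' Family pedigree
#'
#' A validated family graph. `individuals` is a data frame with columns
#' `id`, `father`, `mother` (`NA` for founders/married-in parents not in the
#' graph), `sex` (`"male"`, `"female"`, `"unknown"`), `affected`
#' (`"yes"`, `"no"`, `"unknown"`) and optionally `age_years`.
#'
#' @param individuals Data frame as described above.
#' @param proband_id Identifier of the index patient (must exist if given).
#' @param family_id Family label.
#' @return Object of class `pedigree`.
#' @export
pedigree <- function(individuals, proband_id = NULL, family_id = "FAM") {
  need <- c("id", "father", "mother", "sex", "affected")
  miss <- setdiff(need, names(individuals))
  if (length(miss)) stop("pedigree: missing columns: ", paste(miss, collapse = ", "))
  ind <- individuals
  ind$id <- as.character(ind$id)
  ind$father <- as.character(ind$father)
  ind$mother <- as.character(ind$mother)
  if (anyDuplicated(ind$id)) stop("pedigree: duplicated individual ids")
  if (!all(ind$sex %in% c("male", "female", "unknown"))) {
    stop("pedigree: sex must be male/female/unknown")
  }
  if (!all(ind$affected %in% c("yes", "no", "unknown"))) {
    stop("pedigree: affected must be yes/no/unknown")
  }
  for (col in c("father", "mother")) {
    ref <- ind[[col]][!is.na(ind[[col]])]
    dangling <- setdiff(ref, ind$id)
    if (length(dangling)) {
      stop(sprintf("pedigree: %s id(s) not in pedigree: %s", col,
                   paste(dangling, collapse = ", ")))
    }
  }
  bad_f <- ind$father[!is.na(ind$father)]
  bad_f <- bad_f[ind$sex[match(bad_f, ind$id)] == "female"]
  if (length(bad_f)) stop("pedigree: female individual listed as father: ",
                          paste(unique(bad_f), collapse = ", "))
  bad_m <- ind$mother[!is.na(ind$mother)]
  bad_m <- bad_m[ind$sex[match(bad_m, ind$id)] == "male"]
  if (length(bad_m)) stop("pedigree: male individual listed as mother: ",
                          paste(unique(bad_m), collapse = ", "))
  assert_acyclic(ind)
  if (!is.null(proband_id)) {
    proband_id <- as.character(proband_id)
    if (!proband_id %in% ind$id) {
      stop("pedigree: proband '", proband_id, "' not in pedigree")
    }
  }
  structure(list(individuals = ind, proband_id = proband_id,
                 family_id = as.character(family_id)),
            class = "pedigree")
}

# Kahn-style peeling: repeatedly remove individuals with no remaining parent;
# leftovers imply a parentage cycle.
assert_acyclic <- function(ind) {
  remaining <- ind$id
  repeat {
    has_parent <- vapply(remaining, function(i) {
      row <- ind[ind$id == i, ]
      (!is.na(row$father) && row$father %in% remaining) ||
        (!is.na(row$mother) && row$mother %in% remaining)
    }, logical(1))
    if (!any(has_parent)) return(invisible(TRUE))
    if (all(has_parent)) {
      stop("pedigree: cyclic parentage involving: ",
           paste(remaining, collapse = ", "))
    }
    remaining <- remaining[has_parent]
  }
}

#' Number of generations in a pedigree
#'
#' Depth of the longest founder-to-descendant chain.
#' @param ped A `pedigree`.
#' @return Integer generation count.
#' @export
pedigree_generations <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ind <- ped$individuals
  depth <- stats::setNames(rep(NA_integer_, nrow(ind)), ind$id)
  gen <- function(i) {
    if (!is.na(depth[i])) return(depth[i])
    row <- ind[ind$id == i, ]
    d <- 1L
    if (!is.na(row$father)) d <- max(d, gen(row$father) + 1L)
    if (!is.na(row$mother)) d <- max(d, gen(row$mother) + 1L)
    depth[i] <<- d
    d
  }
  max(vapply(ind$id, gen, integer(1)))
}

#' Variant carrier genotypes observed in a family
#'
#' @param variant_id Variant label (HGVS c. / p. string).
#' @param genotypes Named character vector, names are individual ids, values
#'   `"het"`, `"ref"` or `"untyped"`.
#' @param protein Optional protein-level HGVS string.
#' @return Object of class `variant_observation`.
#' @export
variant_observation <- function(variant_id, genotypes, protein = NULL) {
  if (is.null(names(genotypes))) stop("genotypes must be named by individual id")
  if (!all(genotypes %in% c("het", "ref", "untyped"))) {
    stop("genotypes must be het/ref/untyped")
  }
  structure(list(variant_id = as.character(variant_id),
                 protein = protein,
                 genotypes = genotypes),
            class = "variant_observation")
}

#' @export
print.pedigree <- function(x, ...) {
  n <- nrow(x$individuals)
  cat(sprintf("<pedigree> family %s: %d individuals (%d affected), %d generations\n",
              x$family_id, n, sum(x$individuals$affected == "yes"),
              pedigree_generations(x)))
  if (!is.null(x$proband_id)) cat("  proband:", x$proband_id, "\n")
  invisible(x)
}
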