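#' Family-history risk stratification
#'
#' A configurable rules engine stratifies each pedigree into one of three
#' cohorts: \code{increased} familial cancer risk (at least one rule of the
#' ruleset fires), \code{average} (history available, no rule fires) or
#' \code{not_available} (no family history collected). The shipped default
#' ruleset approximates clinical testing criteria for hereditary
#' breast/ovarian and colorectal cancer; every fired rule is recorded so a
#' stratification is always auditable. Assessments where a rule fires only
#' because an unknown diagnosis age was allowed to stand in for an age
#' requirement are flagged \code{ambiguous}.
#'
#' @name fh-risk
NULL

#' Load a family-history ruleset
#'
#' @param path ruleset YAML; defaults to the packaged ruleset.
#' @return list with \code{options} and \code{rules}.
#' @export
load_fh_ruleset <- function(path = fhc_extdata("fh_rules.yaml")) {
  rs <- yaml::read_yaml(path)
  if (is.null(rs$rules) || !length(rs$rules)) fhc_config_error("ruleset has no rules")
  ids <- vapply(rs$rules, function(r) r$id %||% NA_character_, "")
  if (anyNA(ids) || anyDuplicated(ids)) fhc_config_error("every rule needs a unique id")
  rs$options <- rs$options %||% list(include_third_degree = FALSE)
  rs
}

# evaluate one rule over a flat cases table; returns per-participant
# tibble(participant_id, strict, relaxed)
eval_rule <- function(cases, rule, include_third_degree = FALSE) {
  degrees <- unlist(rule$degrees %||% c(1, 2))
  if (include_third_degree) degrees <- union(degrees, 3)
  sub <- cases[!is.na(cases$condition) & cases$is_cancer &
                 cases$condition %in% unlist(rule$cancers) &
                 cases$degree %in% degrees, , drop = FALSE]
  if (!is.null(rule$sex)) sub <- sub[sub$sex == rule$sex, , drop = FALSE]
  ids <- unique(cases$participant_id)
  none <- tibble::tibble(participant_id = ids, strict = FALSE, relaxed = FALSE)
  if (nrow(sub) == 0) return(none)

  min_count <- rule$min_count %||% 1
  if (is.null(rule$age_max)) {
    age_strict <- rep(TRUE, nrow(sub))
  } else if (isTRUE(rule$age_inclusive)) {
    age_strict <- sub$age_known & sub$age <= rule$age_max
  } else {
    age_strict <- sub$age_known & sub$age < rule$age_max
  }
  # unknown-age relaxation is only available to count-based rules
  age_relaxed <- if (min_count >= 2) age_strict | !sub$age_known else age_strict
  age_need <- if (is.null(rule$age_max)) 0 else (rule$age_min_count %||% min_count)

  if (isTRUE(rule$same_lineage)) {
    both <- sub$lineage == "both"
    sub2 <- rbind(sub[!both, ], sub[both, ], sub[both, ])
    side <- c(sub$lineage[!both], rep(c("maternal", "paternal"), each = sum(both)))
    age_strict2 <- c(age_strict[!both], rep(age_strict[both], 2))
    age_relaxed2 <- c(age_relaxed[!both], rep(age_relaxed[both], 2))
    key <- paste(sub2$participant_id, side)
    n <- tapply(rep(1, nrow(sub2)), key, sum)
    ns <- tapply(age_strict2, key, sum)
    nr <- tapply(age_relaxed2, key, sum)
    fired_s <- n >= min_count & ns >= age_need
    fired_r <- n >= min_count & nr >= age_need
    pid_of <- sub("\\s(maternal|paternal)$", "", names(n))
    strict_ids <- unique(pid_of[fired_s])
    relaxed_ids <- unique(pid_of[fired_r])
  } else {
    n <- tapply(rep(1, nrow(sub)), sub$participant_id, sum)
    ns <- tapply(age_strict, sub$participant_id, sum)
    nr <- tapply(age_relaxed, sub$participant_id, sum)
    strict_ids <- names(n)[n >= min_count & ns >= age_need]
    relaxed_ids <- names(n)[n >= min_count & nr >= age_need]
  }
  tibble::tibble(participant_id = ids,
                 strict = ids %in% strict_ids,
                 relaxed = ids %in% relaxed_ids)
}

#' Assess family-history cancer risk for a whole cohort
#'
#' Vectorised rule evaluation over the flat cases table of many pedigrees.
#' Rule firing is deterministic and independent of the order of relatives;
#' adding an affected relative can only move a participant from average to
#' increased, never the reverse.
#'
#' @param cases row-bound relatives tibble (see \code{\link{read_pedigrees}}).
#' @param fh tibble (participant_id, fh_available) covering every
#'   participant to assess.
#' @param ruleset from \code{\link{load_fh_ruleset}}.
#' @return tibble: participant_id, \code{fh_cohort}
#'   (increased/average/not_available), \code{triggered_rules}
#'   (semicolon-separated ids), \code{ambiguous}.
#' @export
assess_fh_cohort <- function(cases, fh, ruleset = load_fh_ruleset()) {
  ids <- fh$participant_id
  strict <- matrix(FALSE, length(ids), length(ruleset$rules),
                   dimnames = list(ids, vapply(ruleset$rules, `[[`, "", "id")))
  relaxed <- strict
  if (nrow(cases)) {
    inc3 <- isTRUE(ruleset$options$include_third_degree)
    for (j in seq_along(ruleset$rules)) {
      res <- eval_rule(cases, ruleset$rules[[j]], inc3)
      m <- match(res$participant_id, ids)
      ok <- !is.na(m)
      strict[m[ok], j] <- res$strict[ok]
      relaxed[m[ok], j] <- res$relaxed[ok]
    }
  }
  fired_any <- rowSums(relaxed) > 0
  cohort <- ifelse(!fh$fh_available, "not_available",
                   ifelse(fired_any, "increased", "average"))
  triggered <- apply(relaxed, 1, function(r) paste(colnames(relaxed)[r], collapse = ";"))
  triggered[cohort != "increased"] <- ""
  ambiguous <- fired_any & rowSums(strict) == 0 & fh$fh_available
  tibble::tibble(participant_id = ids, fh_cohort = cohort,
                 triggered_rules = unname(triggered), ambiguous = unname(ambiguous))
}

#' Assess family-history cancer risk for one pedigree
#'
#' @param pedigree an \code{fhc_pedigree}.
#' @param ruleset from \code{\link{load_fh_ruleset}}.
#' @return one-row assessment tibble (see \code{\link{assess_fh_cohort}}).
#' @export
#' @examples
#' ped <- parse_pedigree(list(
#'   participant_id = "P1", fh_available = TRUE,
#'   relatives = list(list(relation = "mother", sex = "F",
#'     diagnoses = list(list(condition = "breast", age = 41))))))
#' assess_fh_risk(ped)$fh_cohort  # "increased"
assess_fh_risk <- function(pedigree, ruleset = load_fh_ruleset()) {
  fh <- tibble::tibble(participant_id = pedigree$participant_id,
                       fh_available = pedigree$fh_available)
  assess_fh_cohort(pedigree$relatives, fh, ruleset)
}

#' Summarise cancers reported by a set of families
#'
#' For the increased-risk subset (or any set of pedigrees): the frequency of
#' each reported cancer type and the fraction of families reporting more
#' than one distinct type. By default percentages are per cancer report
#' (denominator: all cancer reports across the families, the
#' unknown-type category retained); \code{per_family = TRUE} counts each
#' (family, type) pair once instead.
#'
#' @param cases row-bound relatives tibble of the subset.
#' @param per_family denominator switch, default FALSE (per report).
#' @return list with \code{cancer_table} (tibble condition, n, pct),
#'   \code{n_families}, \code{n_reports},
#'   \code{multi_cancer_family_fraction}; an empty subset yields an empty
#'   summary with \code{n_families = 0}.
#' @export
summarize_family_cancers <- function(cases, per_family = FALSE) {
  ca <- cases[!is.na(cases$condition) & cases$is_cancer, , drop = FALSE]
  fams <- unique(cases$participant_id)
  if (nrow(ca) == 0) {
    return(list(cancer_table = tibble::tibble(condition = character(),
                                              n = integer(), pct = double()),
                n_families = length(fams), n_reports = 0L,
                multi_cancer_family_fraction = NA_real_))
  }
  if (per_family) ca <- ca[!duplicated(ca[, c("participant_id", "condition")]), ]
  tab <- sort(table(ca$condition), decreasing = TRUE)
  types_per_family <- tapply(ca$condition, ca$participant_id,
                             function(x) length(unique(x)))
  list(
    cancer_table = tibble::tibble(condition = names(tab), n = as.integer(tab),
                                  pct = pct(as.integer(tab), sum(tab))),
    n_families = length(fams),
    n_reports = nrow(ca),
    multi_cancer_family_fraction = sum(types_per_family > 1) / length(fams)
  )
}
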