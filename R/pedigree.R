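#' Pedigrees and family health histories
#'
#' A pedigree captures up to four generations of family health information —
#' children to grandparents and cousins — as reported by one study
#' participant (the proband). Each relative carries zero or more diagnoses;
#' diagnosis ages may be exact years, decade bands ("50s") or unknown.
#' Relation determines degree (1st: parent/sibling/child; 2nd:
#' grandparent/aunt-uncle; 3rd: cousin) and lineage (maternal/paternal;
#' siblings and children belong to both sides).
#'
#' Two on-disk formats are supported: a pedigree JSON (one object per
#' participant with a \code{relatives} array) and an extended PED dialect
#' (the standard six columns plus a semicolon-separated
#' \code{condition@age} phenotype column, relations inferred from the
#' pedigree links; the proband is the individual whose id equals the family
#' id).
#'
#' @name pedigrees
NULL

RELATION_LEVELS <- c("self", "father", "mother", "sibling", "child",
                     "grandparent", "aunt_uncle", "cousin")
LINEAGE_LEVELS <- c("maternal", "paternal", "both")
SEX_LEVELS <- c("M", "F", "unknown")

#' Controlled cancer vocabulary
#'
#' Terms recognised as cancers by the family-history rules engine; any other
#' condition term is stored but ignored by the cancer ruleset (free-text
#' conditions can be forced with an explicit \code{is_cancer} flag in the
#' JSON).
#'
#' @return character vector of cancer terms (including
#'   \code{"unknown_cancer"} for reports where the type was not known).
#' @export
cancer_terms <- function() {
  c("breast", "ovarian", "colorectal", "endometrial", "gastric", "urothelial",
    "bladder", "small_bowel", "prostate", "pancreatic", "lung", "liver",
    "thyroid", "cervical", "leukemia", "lymphoma", "melanoma", "brain",
    "kidney", "sarcoma", "skin", "unknown_cancer")
}

relation_degree <- function(relation) {
  c(self = 0L, father = 1L, mother = 1L, sibling = 1L, child = 1L,
    grandparent = 2L, aunt_uncle = 2L, cousin = 3L)[relation]
}

# lineage implied by relation, or taken from the stated side
resolve_lineage <- function(relation, lineage) {
  implied <- c(father = "paternal", mother = "maternal", sibling = "both",
               child = "both", self = "both")
  out <- ifelse(relation %in% names(implied), implied[relation], lineage)
  unname(out)
}

#' Parse a diagnosis age (years, decade band or unknown)
#'
#' Decade bands map to their midpoint ("50s" is 55); unknown ages become NA.
#'
#' @param x character or numeric vector.
#' @return numeric vector of representative ages (NA when unknown).
#' @export
parse_age <- function(x) {
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  dec <- !is.na(x) & grepl("^[1-9][0-9]?0s$", x)
  out[dec] <- as.numeric(sub("s$", "", x[dec])) + 5
  out[!is.na(x) & x %in% c("unknown", "?", "")] <- NA
  out
}

new_pedigree <- function(participant_id, fh_available, relatives) {
  structure(list(participant_id = participant_id,
                 fh_available = fh_available,
                 relatives = relatives),
            class = "fhc_pedigree")
}

empty_cases_tbl <- function() {
  tibble::tibble(
    participant_id = character(), relative_id = character(),
    relation = character(), degree = integer(), lineage = character(),
    sex = character(), deceased = logical(), condition = character(),
    is_cancer = logical(), age = double(), age_known = logical()
  )
}

validate_relatives <- function(participant_id, rel) {
  bad <- setdiff(unique(rel$relation), RELATION_LEVELS)
  if (length(bad)) {
    fhc_data_error(participant_id, ": unknown relation term(s): ",
                   paste(bad, collapse = ", "))
  }
  for (r in c("father", "mother")) {
    n <- length(unique(rel$relative_id[rel$relation == r]))
    if (n > 1) fhc_data_error(participant_id, ": pedigree has ", n, " ", r, "s")
  }
  need_side <- rel$relation %in% c("grandparent", "aunt_uncle", "cousin")
  if (any(need_side & !(rel$lineage %in% c("maternal", "paternal")))) {
    fhc_data_error(participant_id,
                   ": grandparents, aunts/uncles and cousins need a maternal/paternal lineage")
  }
  invisible(rel)
}

#' Parse a pedigree JSON file
#'
#' Expected shape: \code{{"participant_id": ..., "fh_available": true,
#' "relatives": [{"id", "relation", "lineage", "sex", "deceased",
#' "diagnoses": [{"condition", "age", "is_cancer"}]}]}}. Relations, degrees
#' and lineages are resolved and decade-band ages normalised to midpoints.
#'
#' @param path JSON file (or a pre-parsed list, for programmatic use).
#' @return an \code{fhc_pedigree}: participant id, \code{fh_available}, and
#'   a flat \code{relatives} tibble with one row per (relative, diagnosis).
#' @export
parse_pedigree <- function(path) {
  obj <- if (is.character(path)) jsonlite::fromJSON(path, simplifyVector = FALSE) else path
  pid <- obj$participant_id %||% fhc_data_error("pedigree JSON lacks participant_id")
  fh <- isTRUE(obj$fh_available %||% TRUE)
  rels <- obj$relatives %||% list()
  if (!fh && length(rels)) {
    fhc_data_error(pid, ": fh_available is false but relatives are present")
  }
  if (length(rels) == 0) {
    return(new_pedigree(pid, fh, empty_cases_tbl()))
  }
  rows <- lapply(seq_along(rels), function(i) {
    r <- rels[[i]]
    relation <- as.character(r$relation %||% NA)
    dx <- r$diagnoses %||% list()
    n <- max(1L, length(dx))
    cond <- vapply(seq_len(n), function(j) {
      if (j > length(dx)) NA_character_ else as.character(dx[[j]]$condition %||% NA)
    }, "")
    age_raw <- vapply(seq_len(n), function(j) {
      if (j > length(dx)) NA_character_ else as.character(dx[[j]]$age %||% NA)
    }, "")
    canc <- vapply(seq_len(n), function(j) {
      if (j > length(dx)) FALSE
      else if (!is.null(dx[[j]]$is_cancer)) isTRUE(dx[[j]]$is_cancer)
      else (dx[[j]]$condition %||% "") %in% cancer_terms()
    }, TRUE)
    tibble::tibble(
      participant_id = pid,
      relative_id = as.character(r$id %||% paste0("r", i)),
      relation = relation,
      degree = NA_integer_,
      lineage = as.character(r$lineage %||% NA),
      sex = as.character(r$sex %||% "unknown"),
      deceased = isTRUE(r$deceased),
      condition = cond,
      is_cancer = canc,
      age = parse_age(age_raw),
      age_known = !is.na(parse_age(age_raw))
    )
  })
  rel <- dplyr::bind_rows(rows)
  validate_relatives(pid, rel)
  rel$lineage <- resolve_lineage(rel$relation, rel$lineage)
  rel$degree <- unname(relation_degree(rel$relation))
  bad_sex <- setdiff(unique(rel$sex), SEX_LEVELS)
  if (length(bad_sex)) fhc_data_error(pid, ": unknown sex value(s): ", paste(bad_sex, collapse = ", "))
  new_pedigree(pid, fh, rel)
}

#' Write a pedigree to JSON
#'
#' Inverse of \code{\link{parse_pedigree}} up to age normalisation (decade
#' bands are written back as their midpoint years).
#'
#' @param pedigree an \code{fhc_pedigree}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  rel <- pedigree$relatives
  by_rel <- split(rel, factor(rel$relative_id, levels = unique(rel$relative_id)))
  relatives <- lapply(by_rel, function(g) {
    dx <- g[!is.na(g$condition), c("condition", "age", "is_cancer")]
    list(
      id = g$relative_id[1], relation = g$relation[1],
      lineage = if (g$relation[1] %in% c("grandparent", "aunt_uncle", "cousin")) g$lineage[1] else NULL,
      sex = g$sex[1], deceased = g$deceased[1],
      diagnoses = if (nrow(dx) == 0) list() else
        lapply(seq_len(nrow(dx)), function(j) {
          list(condition = dx$condition[j],
               age = if (is.na(dx$age[j])) NULL else dx$age[j],
               is_cancer = dx$is_cancer[j])
        })
    )
  })
  obj <- list(participant_id = pedigree$participant_id,
              fh_available = pedigree$fh_available,
              relatives = unname(relatives))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a directory (or list) of pedigree JSON files as one cohort
#'
#' @param paths a directory containing \code{*.json} pedigrees, or a
#'   character vector of files.
#' @return list with \code{fh} (tibble participant_id, fh_available) and
#'   \code{cases} (row-bound relatives tibble across all pedigrees).
#' @export
read_pedigrees <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.json$", full.names = TRUE)
  }
  if (length(paths) == 0) fhc_data_error("no pedigree JSON files found")
  peds <- lapply(paths, parse_pedigree)
  list(
    fh = tibble::tibble(
      participant_id = vapply(peds, function(p) p$participant_id, ""),
      fh_available = vapply(peds, function(p) p$fh_available, TRUE)
    ),
    cases = dplyr::bind_rows(lapply(peds, function(p) p$relatives))
  )
}

# ---- extended PED dialect ------------------------------------------------

PED_COLS <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "conditions")

format_conditions <- function(g) {
  dx <- g[!is.na(g$condition), , drop = FALSE]
  if (nrow(dx) == 0) return("-")
  paste(sprintf("%s@%s", dx$condition,
                ifelse(dx$age_known, as.character(dx$age), "?")),
        collapse = ";")
}

#' Write a pedigree in the extended PED dialect
#'
#' Standard six columns (family, individual, father, mother, sex, and a
#' placeholder affection status replaced by the condition column):
#' \code{family_id individual_id father_id mother_id sex conditions} where
#' \code{conditions} is semicolon-separated \code{condition@age} ("-" if
#' none, "?" for unknown age). Linking individuals (parents, grandparents)
#' are synthesised as needed so that relations can be re-inferred from the
#' links alone; the proband row carries \code{individual_id == family_id}.
#'
#' @param pedigree an \code{fhc_pedigree}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ped <- function(pedigree, path) {
  pid <- pedigree$participant_id
  rel <- pedigree$relatives
  ids <- new.env(parent = emptyenv())
  rows <- list()
  add <- function(iid, dad = "0", mom = "0", sex = "unknown", cond = "-") {
    if (!is.null(ids[[iid]])) return(invisible(NULL))
    ids[[iid]] <- TRUE
    rows[[length(rows) + 1]] <<- data.frame(
      family_id = pid, individual_id = iid, father_id = dad, mother_id = mom,
      sex = c(M = "1", F = "2", unknown = "0")[sex], conditions = cond,
      stringsAsFactors = FALSE)
  }
  by_rel <- split(rel, factor(rel$relative_id, levels = unique(rel$relative_id)))
  one <- function(relation, side = NULL) {
    keep <- vapply(by_rel, function(g) {
      g$relation[1] == relation && (is.null(side) || g$lineage[1] == side)
    }, TRUE)
    by_rel[keep]
  }
  # founders first: grandparents (placeholders if absent but needed)
  need_side <- function(side) {
    length(one("grandparent", side)) > 0 || length(one("aunt_uncle", side)) > 0 ||
      length(one("cousin", side)) > 0
  }
  gp_ids <- list(maternal = c("MGF", "MGM"), paternal = c("PGF", "PGM"))
  for (side in c("maternal", "paternal")) {
    gps <- one("grandparent", side)
    if (length(gps) || need_side(side)) {
      slots <- gp_ids[[side]]
      used <- c(FALSE, FALSE)  # grandfather, grandmother
      for (g in gps) {
        slot <- if (g$sex[1] == "M") 1 else 2
        if (used[slot]) slot <- which(!used)[1]
        used[slot] <- TRUE
        add(slots[slot], sex = g$sex[1], cond = format_conditions(g))
      }
      for (s in which(!used)) add(gp_ids[[side]][s], sex = c("M", "F")[s])
    }
  }
  # parents are always written so the proband row has links
  dad <- one("father"); mom <- one("mother")
  pg <- if (!is.null(ids[["PGF"]])) c("PGF", "PGM") else c("0", "0")
  mg <- if (!is.null(ids[["MGF"]])) c("MGF", "MGM") else c("0", "0")
  add("FATHER", pg[1], pg[2], "M",
      if (length(dad)) format_conditions(dad[[1]]) else "-")
  add("MOTHER", mg[1], mg[2], "F",
      if (length(mom)) format_conditions(mom[[1]]) else "-")
  # proband
  add(pid, "FATHER", "MOTHER", "unknown")
  with_prefix <- function(prefix, id) {
    if (startsWith(id, prefix)) id else paste0(prefix, id)
  }
  # siblings and children
  for (g in one("sibling")) add(with_prefix("SIB_", g$relative_id[1]),
                                "FATHER", "MOTHER", g$sex[1], format_conditions(g))
  for (g in one("child")) add(with_prefix("CHILD_", g$relative_id[1]), pid, "0",
                              g$sex[1], format_conditions(g))
  # aunts/uncles and their children (cousins)
  au_by_side <- list(maternal = character(), paternal = character())
  for (side in c("maternal", "paternal")) {
    slots <- gp_ids[[side]]
    for (g in one("aunt_uncle", side)) {
      iid <- with_prefix(paste0(toupper(substr(side, 1, 1)), "AU_"), g$relative_id[1])
      add(iid, slots[1], slots[2], g$sex[1], format_conditions(g))
      au_by_side[[side]] <- c(au_by_side[[side]], iid)
    }
    cz <- one("cousin", side)
    if (length(cz) && length(au_by_side[[side]]) == 0) {
      iid <- paste0(toupper(substr(side, 1, 1)), "AU_LINK")
      add(iid, slots[1], slots[2], "unknown")
      au_by_side[[side]] <- iid
    }
    for (g in cz) {
      au <- au_by_side[[side]][1]
      add(with_prefix("COUSIN_", g$relative_id[1]),
          au, "0", g$sex[1], format_conditions(g))
    }
  }
  out <- dplyr::bind_rows(rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

parse_conditions <- function(pid, relative_id, relation, lineage, sex, txt) {
  base <- tibble::tibble(
    participant_id = pid, relative_id = relative_id, relation = relation,
    degree = unname(relation_degree(relation)),
    lineage = resolve_lineage(relation, lineage),
    sex = sex, deceased = FALSE,
    condition = NA_character_, is_cancer = FALSE,
    age = NA_real_, age_known = FALSE
  )
  if (txt %in% c("-", "", NA)) return(base)
  parts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  cond <- sub("@.*$", "", parts)
  age <- parse_age(sub("^.*@", "", parts))
  out <- base[rep(1, length(parts)), ]
  out$condition <- cond
  out$is_cancer <- cond %in% cancer_terms()
  out$age <- age
  out$age_known <- !is.na(age)
  out
}

#' Parse an extended PED file into a pedigree
#'
#' Relations are inferred from the links: parents of the proband, their
#' parents (grandparents, sided), co-children of the proband's parents
#' (siblings), children of the proband, other children of grandparents
#' (aunts/uncles) and their children (cousins). Individuals that cannot be
#' placed relative to the proband raise a structure error.
#'
#' @param path extended PED file (one family).
#' @return an \code{fhc_pedigree}.
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = PED_COLS, colClasses = "character")
  fam <- unique(df$family_id)
  if (length(fam) != 1) fhc_data_error("extended PED must contain exactly one family")
  pid <- fam
  if (!pid %in% df$individual_id) {
    fhc_data_error("no proband row (individual_id == family_id) in ", path)
  }
  pr <- df[df$individual_id == pid, ]
  sex_of <- function(s) c(`1` = "M", `2` = "F", `0` = "unknown")[s]
  parent_of <- function(iid) df[df$individual_id == iid, c("father_id", "mother_id")]

  relation_for <- function(iid) {
    if (iid == pid) return(NULL)
    row <- df[df$individual_id == iid, ]
    if (iid == pr$father_id) return(list("father", NA))
    if (iid == pr$mother_id) return(list("mother", NA))
    for (side in c("paternal", "maternal")) {
      par <- if (side == "paternal") pr$father_id else pr$mother_id
      if (par == "0") next
      pp <- parent_of(par)
      if (nrow(pp) && iid %in% unlist(pp)) return(list("grandparent", side))
    }
    if ((row$father_id != "0" && row$father_id == pr$father_id) ||
        (row$mother_id != "0" && row$mother_id == pr$mother_id)) {
      return(list("sibling", NA))
    }
    if (row$father_id == pid || row$mother_id == pid) return(list("child", NA))
    for (side in c("paternal", "maternal")) {
      par <- if (side == "paternal") pr$father_id else pr$mother_id
      if (par == "0") next
      pp <- parent_of(par)
      if (!nrow(pp)) next
      gp <- setdiff(unlist(pp), "0")
      if (length(gp) && (row$father_id %in% gp || row$mother_id %in% gp)) {
        return(list("aunt_uncle", side))
      }
      aus <- df$individual_id[(df$father_id %in% gp | df$mother_id %in% gp) &
                                df$individual_id != par]
      if (row$father_id %in% aus || row$mother_id %in% aus) {
        return(list("cousin", side))
      }
    }
    fhc_data_error(pid, ": individual ", iid, " cannot be related to the proband")
  }

  rows <- list()
  for (i in seq_len(nrow(df))) {
    iid <- df$individual_id[i]
    rl <- relation_for(iid)
    if (is.null(rl)) next
    rows[[length(rows) + 1]] <- parse_conditions(
      pid, iid, rl[[1]], rl[[2]], unname(sex_of(df$sex[i])), df$conditions[i])
  }
  rel <- dplyr::bind_rows(rows)
  validate_relatives(pid, rel)
  new_pedigree(pid, TRUE, rel)
}

#' @export
print.fhc_pedigree <- function(x, ...) {
  n_rel <- length(unique(x$relatives$relative_id))
  n_ca <- sum(x$relatives$is_cancer, na.rm = TRUE)
  cat("<fhc_pedigree> ", x$participant_id,
      if (!x$fh_available) " (family history not available)" else
        sprintf(": %d relatives, %d cancer report(s)", n_rel, n_ca), "\n", sep = "")
  invisible(x)
}
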