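#' Gene panel handling
#'
#' The unit of scoping for all variant triage is a cancer gene panel: one row
#' per gene with its inheritance mode, whether haploinsufficiency is an
#' established disease mechanism (the prerequisite for treating
#' loss-of-function variants as pathogenic candidates), membership in the
#' ACMG secondary-findings (SF) cancer gene subset, and the cancer types the
#' gene predisposes to. The package ships a 95-gene default panel
#' (25 of them SF genes) as a tab-separated file; it is a documented
#' synthetic reconstruction of a typical germline cancer panel, not a copy
#' of any proprietary list.
#'
#' @name gene-panel
NULL

PANEL_COLUMNS <- c("symbol", "inheritance", "haploinsufficient", "acmg_sf",
                   "cancer_types", "transcript")
INHERITANCE_LEVELS <- c("AD", "AR", "XL")
HAPLO_LEVELS <- c("yes", "no", "unknown")

#' Load and validate a gene panel
#'
#' Reads a tab-separated panel file (columns \code{symbol}, \code{inheritance}
#' (AD/AR/XL), \code{haploinsufficient} (yes/no/unknown), \code{acmg_sf}
#' (logical), \code{cancer_types} (semicolon-separated), optional
#' \code{transcript}) or a YAML file with one mapping per gene carrying the
#' same fields. Duplicated symbols, missing required columns and unknown
#' enum values are configuration errors.
#'
#' @param path panel file (.tsv/.txt or .yaml/.yml). Defaults to the packaged
#'   95-gene panel.
#' @return a tibble of validated panel entries (class \code{fhc_panel}).
#' @export
#' @examples
#' panel <- load_panel()
#' nrow(panel)                  # 95
#' nrow(subset_acmg_sf(panel))  # 25
load_panel <- function(path = fhc_extdata("cancer_panel_95.tsv")) {
  if (!file.exists(path)) fhc_config_error("panel file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    if (length(raw) == 0) fhc_config_error("panel file is empty: ", path)
    df <- tibble::tibble(
      symbol = vapply(raw, function(g) as.character(g$symbol %||% NA), ""),
      inheritance = vapply(raw, function(g) as.character(g$inheritance %||% NA), ""),
      haploinsufficient = vapply(raw, function(g) as.character(g$haploinsufficient %||% NA), ""),
      acmg_sf = vapply(raw, function(g) isTRUE(g$acmg_sf), TRUE),
      cancer_types = vapply(raw, function(g) paste(unlist(g$cancer_types), collapse = ";"), ""),
      transcript = vapply(raw, function(g) as.character(g$transcript %||% NA), "")
    )
  } else {
    df <- tryCatch(
      readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character())),
      error = function(e) fhc_config_error("cannot parse panel file ", path, ": ", conditionMessage(e))
    )
    if (nrow(df) == 0) fhc_config_error("panel file is empty: ", path)
    if (!"transcript" %in% names(df)) df$transcript <- NA_character_
    df$acmg_sf <- toupper(trimws(df$acmg_sf %||% "")) %in% c("TRUE", "T", "YES", "1")
  }
  validate_panel(df)
}

#' Validate a panel data frame
#'
#' @param df data frame with the panel columns.
#' @return the validated panel tibble, invisibly classed \code{fhc_panel}.
#' @export
validate_panel <- function(df) {
  missing <- setdiff(setdiff(PANEL_COLUMNS, "transcript"), names(df))
  if (length(missing)) {
    fhc_config_error("panel is missing required field(s): ", paste(missing, collapse = ", "))
  }
  df <- tibble::as_tibble(df)[, PANEL_COLUMNS]
  dup <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup)) {
    fhc_config_error("duplicated gene symbol(s) in panel: ", paste(dup, collapse = ", "))
  }
  if (any(is.na(df$symbol) | df$symbol == "")) fhc_config_error("panel has empty gene symbols")
  bad <- setdiff(unique(df$inheritance), INHERITANCE_LEVELS)
  if (length(bad)) fhc_config_error("unknown inheritance value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$haploinsufficient), HAPLO_LEVELS)
  if (length(bad)) fhc_config_error("unknown haploinsufficient value(s): ", paste(bad, collapse = ", "))
  if (!is.logical(df$acmg_sf)) fhc_config_error("acmg_sf must be logical")
  class(df) <- c("fhc_panel", class(df))
  df
}

#' Write a panel back to a tab-separated file
#'
#' \code{load_panel(write_panel(p, f))} round-trips to an identical panel.
#'
#' @param panel validated panel.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- as.data.frame(panel)[, PANEL_COLUMNS]
  out$acmg_sf <- ifelse(out$acmg_sf, "TRUE", "FALSE")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Subset a panel to its ACMG secondary-findings cancer genes
#'
#' Returns exactly the entries flagged \code{acmg_sf}, order preserved.
#' Idempotent.
#'
#' @param panel validated panel.
#' @return panel tibble restricted to SF genes.
#' @export
subset_acmg_sf <- function(panel) {
  panel[panel$acmg_sf, , drop = FALSE]
}
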