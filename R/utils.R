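#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble add_row
#' @import dplyr
#' @importFrom purrr map map_chr map_lgl map_int map_dbl keep discard compact
#' @importFrom stringr str_detect str_replace_all str_trim
NULL

# SNOMED CT identifiers are kept as digit strings end-to-end: full SCTIDs
# exceed the 53-bit range where doubles are exact, and the canonical ordering
# used by the normal form is lexicographic, not numeric.
is_sctid <- function(x) {
  is.character(x) & !is.na(x) & nzchar(x) & grepl("^[0-9]+$", x)
}

assert_sctid <- function(x, what = "identifier") {
  bad <- x[!is_sctid(x)]
  if (length(bad) > 0) {
    abort(sprintf("invalid %s (must be a non-empty digit string): %s",
                  what, paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(x)
}

# Well-known SNOMED CT metadata identifiers used throughout.
SCT_IS_A <- "116680003"
SCT_PRIMITIVE <- "900000000000074008"
SCT_FULLY_DEFINED <- "900000000000073002"
SCT_ROOT <- "138875005"
SCT_ATTRIBUTE <- "246061005"
SCT_CONCEPT_MODEL_ATTRIBUTE <- "410662002"
SCT_FSN_TYPE <- "900000000000003001"
SCT_DEFAULT_MODULE <- "900000000000207008"
SCT_STATED <- "900000000000011006"
SCT_EXISTENTIAL_MODIFIER <- "900000000000451002"

# Reserved role name used to desugar role groups into plain existentials.
RG_ROLE <- "RG"
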