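# Code dictionary: named sets of (code_system, code) pairs driving every
# rule in the pipeline. Real national-claims code lists are access-restricted,
# so the shipped default uses documented placeholder CCAM codes plus public
# ATC molecule codes; a site can swap in its own lists via JSON config
# without touching any logic.

SURGERY_SET_NAMES <- c(
  "surgery_partial_with_axillary", "surgery_partial_without_axillary",
  "surgery_total_with_axillary", "surgery_total_without_axillary",
  "axillary_only"
)

ET_MOLECULE_SET_NAMES <- c("tamoxifen", "aromatase_inhibitor", "gnrh_agonist")

REQUIRED_SET_NAMES <- c(
  "bc_diagnosis", "node_disease", "metastasis", "other_cancer",
  SURGERY_SET_NAMES, "radiotherapy", "ct_session",
  "anthracycline", "docetaxel", "paclitaxel", "other_ct_molecule",
  ET_MOLECULE_SET_NAMES, "trastuzumab", "pertuzumab",
  "breast_biopsy", "breast_cytology", "breast_imaging"
)

#' Default code dictionary
#'
#' Named code sets, each a character vector of `"SYSTEM:CODE"` strings over
#' the systems ICD10, CCAM, ATC and LTI_ICD10. CCAM entries are synthetic
#' placeholders (the operational lists used on real claims are restricted);
#' ATC entries are the public WHO codes for the molecules concerned.
#' CIP/UCD drug codes are assumed normalised to ATC at ingestion.
#'
#' @return an object of class `code_dictionary`: a named list of code sets.
#' @export
#' @examples
#' d <- default_code_dictionary()
#' names(d)
#' d$tamoxifen
default_code_dictionary <- function() {
  d <- list(
    bc_diagnosis = c("ICD10:C50", "LTI_ICD10:C50"),
    node_disease = c("ICD10:C773"),
    metastasis   = c("ICD10:C78", "ICD10:C79"),
    other_cancer = c("ICD10:C18", "ICD10:C34", "ICD10:C61"),
    surgery_partial_with_axillary    = c("CCAM:SURG_PM_AX"),
    surgery_partial_without_axillary = c("CCAM:SURG_PM"),
    surgery_total_with_axillary      = c("CCAM:SURG_M_AX"),
    surgery_total_without_axillary   = c("CCAM:SURG_M"),
    axillary_only                    = c("CCAM:SURG_AX"),
    radiotherapy = c("CCAM:RT_SESSION", "ICD10:Z5101"),
    ct_session   = c("CCAM:CT_SESSION", "ICD10:Z511"),
    anthracycline     = c("ATC:L01DB01", "ATC:L01DB03"),
    docetaxel         = c("ATC:L01CD02"),
    paclitaxel        = c("ATC:L01CD01"),
    other_ct_molecule = c("ATC:L01XA01", "ATC:L01XA02", "ATC:L01BC06"),
    tamoxifen           = c("ATC:L02BA01"),
    aromatase_inhibitor = c("ATC:L02BG03", "ATC:L02BG04", "ATC:L02BG06"),
    gnrh_agonist        = c("ATC:L02AE02", "ATC:L02AE03"),
    trastuzumab = c("ATC:L01XC03"),
    pertuzumab  = c("ATC:L01XC13"),
    breast_biopsy   = c("CCAM:BIOPSY_BREAST"),
    breast_cytology = c("CCAM:CYTO_BREAST"),
    breast_imaging  = c("CCAM:MAMMO", "CCAM:ECHO_BREAST", "CCAM:MRI_BREAST")
  )
  new_code_dictionary(d)
}

new_code_dictionary <- function(sets) {
  validate_code_dictionary(sets)
  structure(sets, class = "code_dictionary")
}

validate_code_dictionary <- function(sets) {
  missing <- setdiff(REQUIRED_SET_NAMES, names(sets))
  if (length(missing)) {
    abort_ctx(paste0("code dictionary is missing set(s): ",
                     paste(missing, collapse = ", ")), "dictionary_error")
  }
  empty <- names(sets)[vapply(sets, length, 1L) == 0]
  if (length(empty)) {
    abort_ctx(paste0("code dictionary set(s) empty: ",
                     paste(empty, collapse = ", ")), "dictionary_error")
  }
  check_disjoint <- function(group, label) {
    all_codes <- unlist(sets[group], use.names = FALSE)
    if (anyDuplicated(all_codes)) {
      abort_ctx(paste0(label, " code sets must be pairwise disjoint (",
                       paste(unique(all_codes[duplicated(all_codes)]),
                             collapse = ", "), ")"), "dictionary_error")
    }
  }
  check_disjoint(SURGERY_SET_NAMES, "surgery")
  check_disjoint(ET_MOLECULE_SET_NAMES, "endocrine-therapy molecule")
  invisible(TRUE)
}

#' Read / write a code dictionary as JSON
#'
#' The on-disk format is a JSON object mapping set name to a list of
#' `"SYSTEM:CODE"` strings.
#'
#' @param path file path of the JSON dictionary.
#' @return `read_code_dictionary()` returns a `code_dictionary`;
#'   `write_code_dictionary()` returns `path` invisibly.
#' @export
read_code_dictionary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_code_dictionary(lapply(raw, as.character))
}

#' @rdname read_code_dictionary
#' @param dictionary a `code_dictionary`.
#' @export
write_code_dictionary <- function(dictionary, path) {
  jsonlite::write_json(unclass(dictionary), path, pretty = TRUE)
  invisible(path)
}

#' Look up one code set
#'
#' @param dictionary a `code_dictionary`.
#' @param name set name, e.g. `"bc_diagnosis"`.
#' @return character vector of `"SYSTEM:CODE"` strings.
#' @export
code_set <- function(dictionary, name) {
  if (!name %in% names(dictionary)) {
    abort_ctx(paste0("unknown code set: ", name), "dictionary_error")
  }
  dictionary[[name]]
}

# All codes in any dictionary set (used to flag unknown codes at load).
all_dictionary_codes <- function(dictionary) {
  unique(unlist(dictionary, use.names = FALSE))
}

# Tag events (tibble with code_system, code) with "SYSTEM:CODE" keys.
event_keys <- function(events) paste0(events$code_system, ":", events$code)

#' @export
print.code_dictionary <- function(x, ...) {
  cat("<code_dictionary> ", length(x), " sets, ",
      length(all_dictionary_codes(x)), " distinct codes\n", sep = "")
  invisible(x)
}
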