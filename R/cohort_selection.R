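# Ordered inclusion/exclusion filters with full attrition accounting.
# A patient failing several filters is attributed to the first applicable
# one, so the per-filter exclusion counts chain deterministically.

FILTER_NAMES <- c(
  "bc_diagnosis_code",    # 1: at least one breast-cancer diagnosis code
  "incidence_window",     # 2: inclusion date inside the incidence window
  "female",               # 3
  "adult",                # 4: age >= 18 at inclusion
  "general_plan",         # 5: general health-insurance plan
  "surgery_within_year",  # 6: breast surgery within a year of inclusion
  "no_other_cancer",      # 7: no concomitant other cancer
  "no_prior_bc",          # 8: no BC code in the look-back year
  "no_metastasis",        # 9: no suspicion of stage IV disease
  "data_quality"          # 10: chronologically consistent record
)

#' Selection configuration
#'
#' Parameters of the ten-filter battery. The metastasis window mirrors the
#' nodal-status window around the index surgery plus the one-year
#' look-back before inclusion.
#'
#' @param incidence_window two dates bounding admissible inclusion dates.
#' @param surgery_lookahead_days days after inclusion within which a breast
#'   surgery must occur (filter 6).
#' @param lookback_days_for_prior_bc look-back horizon for previous
#'   breast-cancer codes (filter 8).
#' @param metastasis_lookback_days,metastasis_lookahead_days bounds of the
#'   stage-IV-suspicion window: `[inclusion - lookback,
#'   index surgery + lookahead]` (filter 9).
#' @param metastasis_set,other_cancer_set dictionary set names.
#' @param quality_rules apply the chronology checks of filter 10.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(incidence_window = as.Date(c("2011-01-01",
                                                          "2017-12-31")),
                             surgery_lookahead_days = 365L,
                             lookback_days_for_prior_bc = 365L,
                             metastasis_lookback_days = 365L,
                             metastasis_lookahead_days = 180L,
                             metastasis_set = "metastasis",
                             other_cancer_set = "other_cancer",
                             quality_rules = TRUE) {
  incidence_window <- as.Date(incidence_window)
  if (surgery_lookahead_days <= 0) {
    abort_ctx("surgery_lookahead_days must be positive", "config_error")
  }
  if (incidence_window[1] >= incidence_window[2]) {
    abort_ctx("incidence window start must precede its end", "config_error")
  }
  structure(list(
    incidence_window = incidence_window,
    surgery_lookahead_days = as.integer(surgery_lookahead_days),
    lookback_days_for_prior_bc = as.integer(lookback_days_for_prior_bc),
    metastasis_lookback_days = as.integer(metastasis_lookback_days),
    metastasis_lookahead_days = as.integer(metastasis_lookahead_days),
    metastasis_set = metastasis_set, other_cancer_set = other_cancer_set,
    quality_rules = isTRUE(quality_rules)), class = "selection_config")
}

# earliest qualifying breast surgery (categories 1-4) per patient within
# [Jan 1 of the inclusion year, inclusion + lookahead]; vectorized
index_surgery_dates <- function(bundle, dictionary,
                                lookahead_days = 365L) {
  breast_sets <- setdiff(SURGERY_SET_NAMES, "axillary_only")
  breast_codes <- unlist(dictionary[breast_sets], use.names = FALSE)
  ev <- bundle$events[event_keys(bundle$events) %in% breast_codes, ,
                     drop = FALSE]
  ev <- dplyr::left_join(
    ev, bundle$patients[, c("patient_id", "inclusion_date")],
    by = "patient_id")
  if (!nrow(ev)) {
    return(tibble::tibble(patient_id = character(),
                          index_date = as.Date(character())))
  }
  year_start <- as.Date(paste0(format(ev$inclusion_date, "%Y"), "-01-01"))
  ev <- ev[ev$event_date >= year_start &
             ev$event_date <= ev$inclusion_date + lookahead_days, ,
           drop = FALSE]
  m <- tapply(as.numeric(ev$event_date), ev$patient_id, min)
  tibble::tibble(patient_id = if (length(m)) names(m) else character(),
                 index_date = as.Date(as.numeric(m),
                                      origin = "1970-01-01"))
}

#' Apply the ten selection filters
#'
#' Applies, in order: (1) at least one breast-cancer diagnosis code;
#' (2) inclusion date inside the incidence window; (3) female sex;
#' (4) age 18 or over at inclusion (rounded year difference); (5) general
#' insurance plan; (6) at least one breast surgery within the year
#' following inclusion; (7) no other-cancer code anywhere in the
#' observation window; (8) no breast-cancer code in the year preceding
#' inclusion; (9) no metastasis code in the stage-IV-suspicion window
#' around diagnosis; (10) a chronologically consistent record (no claims
#' after death, no surgery before birth). Each excluded patient is counted
#' at the first filter that rejects her.
#'
#' @param bundle a [claims_bundle()].
#' @param config a [selection_config()].
#' @param dictionary a `code_dictionary`.
#' @return a list with `included` (character vector of patient ids) and
#'   `attrition`, a tibble with one row per filter: `filter_index`,
#'   `filter_name`, `n_before`, `n_excluded`, `n_after`.
#' @export
#' @examples
#' sim <- simulate_claims(sim_preset("clean_small", n_patients = 30, seed = 1))
#' sel <- apply_filters(sim$bundle)
#' sel$attrition
apply_filters <- function(bundle, config = selection_config(),
                          dictionary = default_code_dictionary()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  p <- bundle$patients
  ev <- bundle$events
  keys <- event_keys(ev)
  n0 <- nrow(p)

  set_codes <- function(name) code_set(dictionary, name)
  ids_with <- function(sel) unique(ev$patient_id[sel])

  bc_codes <- set_codes("bc_diagnosis")
  pass <- list()
  pass[[1]] <- p$patient_id %in% ids_with(keys %in% bc_codes)
  pass[[2]] <- p$inclusion_date >= config$incidence_window[1] &
    p$inclusion_date <= config$incidence_window[2]
  pass[[3]] <- p$sex == "female"
  age_incl <- round_half_up(
    as.numeric(p$inclusion_date - p$birth_date) / 365.25)
  pass[[4]] <- age_incl >= 18
  pass[[5]] <- p$insurance_plan == "general"

  breast_sets <- setdiff(SURGERY_SET_NAMES, "axillary_only")
  breast_codes <- unlist(dictionary[breast_sets], use.names = FALSE)
  surg <- ev[keys %in% breast_codes, c("patient_id", "event_date")]
  surg <- dplyr::left_join(surg,
                           p[, c("patient_id", "inclusion_date")],
                           by = "patient_id")
  ok6 <- unique(surg$patient_id[
    surg$event_date >= surg$inclusion_date &
      surg$event_date <= surg$inclusion_date +
        config$surgery_lookahead_days])
  pass[[6]] <- p$patient_id %in% ok6

  pass[[7]] <- !p$patient_id %in%
    ids_with(keys %in% set_codes(config$other_cancer_set))

  bc_ev <- ev[keys %in% bc_codes, c("patient_id", "event_date")]
  bc_ev <- dplyr::left_join(bc_ev,
                            p[, c("patient_id", "inclusion_date")],
                            by = "patient_id")
  prior <- unique(bc_ev$patient_id[
    bc_ev$event_date >= bc_ev$inclusion_date -
      config$lookback_days_for_prior_bc &
      bc_ev$event_date <= bc_ev$inclusion_date - 1L])
  pass[[8]] <- !p$patient_id %in% prior

  # stage-IV suspicion: metastasis code in [inclusion - lookback,
  # index surgery + lookahead]; patients without an index surgery use the
  # inclusion date as the anchor (they are caught by filter 6 anyway)
  idx <- index_surgery_dates(bundle, dictionary,
                             config$surgery_lookahead_days)
  anchor <- dplyr::left_join(p[, c("patient_id", "inclusion_date")], idx,
                             by = "patient_id")
  anchor$index_date[is.na(anchor$index_date)] <-
    anchor$inclusion_date[is.na(anchor$index_date)]
  met <- ev[keys %in% set_codes(config$metastasis_set),
            c("patient_id", "event_date")]
  met <- dplyr::left_join(met, anchor, by = "patient_id")
  met_ids <- unique(met$patient_id[
    met$event_date >= met$inclusion_date -
      config$metastasis_lookback_days &
      met$event_date <= met$index_date +
        config$metastasis_lookahead_days])
  pass[[9]] <- !p$patient_id %in% met_ids

  if (config$quality_rules) {
    ev_p <- dplyr::left_join(
      ev[, c("patient_id", "event_date")],
      p[, c("patient_id", "birth_date", "death_date")],
      by = "patient_id")
    after_death <- unique(ev_p$patient_id[
      !is.na(ev_p$death_date) & ev_p$event_date > ev_p$death_date])
    before_birth <- unique(ev_p$patient_id[
      ev_p$event_date < ev_p$birth_date])
    pass[[10]] <- !p$patient_id %in% union(after_death, before_birth)
  } else {
    pass[[10]] <- rep(TRUE, n0)
  }

  ok <- rep(TRUE, n0)
  rows <- vector("list", 10L)
  for (f in seq_len(10L)) {
    n_before <- sum(ok)
    fails <- ok & !pass[[f]]
    ok <- ok & pass[[f]]
    rows[[f]] <- tibble::tibble(
      filter_index = f, filter_name = FILTER_NAMES[f],
      n_before = n_before, n_excluded = sum(fails), n_after = sum(ok))
  }
  list(included = p$patient_id[ok], attrition = dplyr::bind_rows(rows))
}
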