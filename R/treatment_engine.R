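# Treatment detection around the index surgery. Every window is a closed
# interval of day offsets relative to the index surgery date; membership is
# a pure function of (event date - index date), so shifting a whole record
# in time changes nothing.

SURGERY_CATEGORIES <- c(
  surgery_total_with_axillary = "mastectomy_with_axillary",
  surgery_total_without_axillary = "mastectomy_without_axillary",
  surgery_partial_with_axillary = "partial_with_axillary",
  surgery_partial_without_axillary = "partial_without_axillary",
  axillary_only = "axillary_only")

CT_REGIMENS <- c("anthracyclines", "anthracyclines/docetaxel",
                 "anthracyclines/paclitaxel", "docetaxel", "paclitaxel",
                 "other", "unknown")
ET_REGIMENS <- c("tamoxifen", "tamoxifen_with_gnrh", "tamoxifen_then_ai",
                 "ai", "ai_with_gnrh", "ai_then_tamoxifen", "others")
TT_COMBINATIONS <- c("anthracyclines/docetaxel-TT",
                     "anthracyclines/paclitaxel-TT", "docetaxel-TT",
                     "paclitaxel-TT (Tolaney)", "TT-ET", "other")

#' Temporal detection windows
#'
#' Closed day-offset intervals relative to the index surgery inside which a
#' session event counts as a breast-cancer treatment: radiotherapy
#' `[-150, +365]`, chemotherapy and anti-HER2 targeted therapy
#' `[-250, +180]`, and the nodal-status window `[-250, +180]`.
#'
#' @param rt,ct,tt,node two-element integer vectors `c(lower, upper)` with
#'   `lower < 0 < upper`.
#' @return a named list of windows.
#' @export
treatment_windows <- function(rt = c(-150L, 365L), ct = c(-250L, 180L),
                              tt = c(-250L, 180L), node = c(-250L, 180L)) {
  w <- list(rt = as.integer(rt), ct = as.integer(ct), tt = as.integer(tt),
            node = as.integer(node))
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2 || w[[nm]][1] >= 0 || w[[nm]][2] <= 0) {
      abort_ctx(paste0("window '", nm, "' must satisfy lower < 0 < upper"),
                "config_error")
    }
  }
  w
}

# annotate surgery events with their 5-way category
surgery_events <- function(events, dictionary) {
  keys <- event_keys(events)
  dates <- as.Date(character())
  cats <- character()
  for (set in SURGERY_SET_NAMES) {
    sel <- keys %in% dictionary[[set]]
    if (any(sel)) {
      dates <- c(dates, events$event_date[sel])
      cats <- c(cats, rep(SURGERY_CATEGORIES[[set]], sum(sel)))
    }
  }
  o <- order(dates)
  tibble::new_tibble(list(date = dates[o], category = cats[o]),
                     nrow = length(o))
}

#' Find the index surgery
#'
#' The index surgery is the earliest breast surgery proper (mastectomy or
#' partial mastectomy, with or without axillary surgery; axillary surgery
#' alone does not qualify) between January 1 of the inclusion year and one
#' year after the inclusion date.
#'
#' @param events one patient's event tibble.
#' @param inclusion_date the patient's inclusion date.
#' @param dictionary a `code_dictionary`.
#' @param lookahead_days search horizon after inclusion (default 365).
#' @return a list with `index_date` and `surgeries`, a tibble of all
#'   5-way-categorised surgery events inside the search window (used for
#'   patient-level type binning).
#' @export
find_index_surgery <- function(events, inclusion_date,
                               dictionary = default_code_dictionary(),
                               lookahead_days = 365L) {
  inclusion_date <- as_date_safe(inclusion_date)
  surg <- surgery_events(events, dictionary)
  lo <- as.Date(paste0(format(inclusion_date, "%Y"), "-01-01"))
  hi <- inclusion_date + lookahead_days
  surg <- surg[surg$date >= lo & surg$date <= hi, , drop = FALSE]
  qualifying <- surg[surg$category != "axillary_only", , drop = FALSE]
  if (!nrow(qualifying)) {
    abort_ctx("no qualifying breast surgery in the index window",
              "no_index_surgery")
  }
  list(index_date = min(qualifying$date), surgeries = surg)
}

#' Bin surgery events to patient-level type
#'
#' The most extensive procedure wins across all surgery events of the
#' index window: any total mastectomy event makes the patient-level breast
#' surgery a mastectomy; any axillary component (including axillary-only
#' events) sets the axillary flag.
#'
#' @param surgeries tibble with a `category` column over the five surgery
#'   categories (as returned by [find_index_surgery()]).
#' @return a list with `breast_type` (`"partial"` or `"mastectomy"`) and
#'   `axillary` (logical).
#' @export
bin_surgery <- function(surgeries) {
  stopifnot(nrow(surgeries) >= 1)
  cats <- surgeries$category
  list(
    breast_type = if (any(cats %in% c("mastectomy_with_axillary",
                                      "mastectomy_without_axillary")))
      "mastectomy" else "partial",
    axillary = any(cats %in% c("mastectomy_with_axillary",
                               "partial_with_axillary", "axillary_only")))
}

#' Assign a treatment setting from session dates
#'
#' Sessions strictly before the index surgery form the neoadjuvant
#' component; sessions on or after it (including same-day) the adjuvant
#' component. Radiotherapy and chemotherapy take
#' `neoadjuvant`/`adjuvant`/`both`; endocrine and targeted therapy take
#' `neoadjuvant_then_adjuvant` whenever any pre-surgery delivery exists,
#' else `adjuvant`.
#'
#' @param session_dates dates of the in-window sessions (non-empty).
#' @param index_date index surgery date.
#' @param modality one of `"RT"`, `"CT"`, `"ET"`, `"TT"`.
#' @return the setting label.
#' @export
assign_setting <- function(session_dates, index_date, modality) {
  stopifnot(length(session_dates) >= 1)
  pre <- any(session_dates < index_date)
  post <- any(session_dates >= index_date)
  if (modality %in% c("RT", "CT")) {
    if (pre && post) "both" else if (pre) "neoadjuvant" else "adjuvant"
  } else {
    if (pre) "neoadjuvant_then_adjuvant" else "adjuvant"
  }
}

empty_course <- function(modality) {
  list(modality = modality, received = FALSE, setting = "none",
       start_date = as.Date(NA), end_date = as.Date(NA),
       regimen = NA_character_)
}

#' Detect a windowed treatment modality
#'
#' A modality is received iff at least one session event falls in the
#' closed window around the index surgery; the course start and end are the
#' first and last in-window sessions.
#'
#' @param events one patient's event tibble.
#' @param index_date index surgery date.
#' @param window `c(lower, upper)` closed day-offset window.
#' @param session_codes character vector of `"SYSTEM:CODE"` session codes.
#' @param modality `"RT"`, `"CT"` or `"TT"` (drives the setting labels).
#' @return a course list: `modality`, `received`, `setting`, `start_date`,
#'   `end_date`, `regimen` (`NA`; filled by the regimen classifiers).
#' @export
detect_windowed_modality <- function(events, index_date, window,
                                     session_codes, modality) {
  dates <- events$event_date[event_keys(events) %in% session_codes]
  off <- as.numeric(dates - as_date_safe(index_date))
  dates <- dates[off >= window[1] & off <= window[2]]
  if (!length(dates)) return(empty_course(modality))
  list(modality = modality, received = TRUE,
       setting = assign_setting(dates, index_date, modality),
       start_date = min(dates), end_date = max(dates),
       regimen = NA_character_, session_dates = sort(dates))
}

#' Classify the chemotherapy regimen
#'
#' Molecule flags are read off coded drug events delivered on the dates of
#' in-window chemotherapy sessions. Paclitaxel-containing regimens are
#' fully identifiable; a session list with no molecule codes at all is
#' `unknown` (anthracycline- and/or docetaxel-only regimens delivered
#' without per-molecule coding); any molecule combination outside the five
#' named ones is `other`.
#'
#' @param events one patient's event tibble.
#' @param session_dates dates of the in-window chemotherapy sessions.
#' @param dictionary a `code_dictionary`.
#' @return one of `anthracyclines`, `anthracyclines/docetaxel`,
#'   `anthracyclines/paclitaxel`, `docetaxel`, `paclitaxel`, `other`,
#'   `unknown`.
#' @export
classify_ct_regimen <- function(events, session_dates,
                                dictionary = default_code_dictionary()) {
  keys <- event_keys(events)
  on_session <- events$event_date %in% session_dates
  has <- function(set) any(on_session & keys %in% code_set(dictionary, set))
  a <- has("anthracycline")
  d <- has("docetaxel")
  p <- has("paclitaxel")
  o <- has("other_ct_molecule")
  if (!a && !d && !p && !o) return("unknown")
  if (p && a && !d && !o) return("anthracyclines/paclitaxel")
  if (p && !a && !d && !o) return("paclitaxel")
  if (d && a && !p && !o) return("anthracyclines/docetaxel")
  if (d && !a && !p && !o) return("docetaxel")
  if (a && !d && !p && !o) return("anthracyclines")
  "other"
}

#' Count treatment cycles per setting
#'
#' Within each setting component (sessions strictly before vs on/after the
#' index surgery), consecutive sessions are merged into one cycle when they
#' are closer than `merge_gap` days; a session at or beyond the gap starts
#' a new cycle. The default 7-day gap is the shortest standard inter-cycle
#' interval (weekly regimens).
#'
#' @param session_dates dates of the in-window sessions.
#' @param index_date index surgery date.
#' @param merge_gap minimum day gap starting a new cycle.
#' @return named list with the cycle count of each non-empty setting
#'   component (`neoadjuvant`, `adjuvant`).
#' @export
count_cycles <- function(session_dates, index_date, merge_gap = 7L) {
  index_date <- as_date_safe(index_date)
  one <- function(dates) {
    if (!length(dates)) return(NULL)
    d <- sort(unique(dates))
    1L + sum(diff(as.numeric(d)) >= merge_gap)
  }
  out <- list(neoadjuvant = one(session_dates[session_dates < index_date]),
              adjuvant = one(session_dates[session_dates >= index_date]))
  out[!vapply(out, is.null, TRUE)]
}

#' Detect endocrine therapy
#'
#' Endocrine therapy is received iff at least one tamoxifen, aromatase
#' inhibitor or GnRH-agonist outpatient delivery occurs from 250 days
#' before the index surgery to the end of observation — except
#' fertility-preservation deliveries: GnRH-agonist dispensings in patients
#' with no tamoxifen/AI delivery ever, occurring within 30 days before
#' chemotherapy start, are discarded. The course ends one dispensing
#' interval (default 30 days, one pack) after the last delivery.
#'
#' @param events one patient's event tibble.
#' @param index_date index surgery date.
#' @param ct_course the patient's chemotherapy course (for the
#'   fertility-preservation rule); may be `NULL`.
#' @param dictionary a `code_dictionary`.
#' @param lookback_days window start before the index surgery.
#' @param pack_days dispensing-interval used for the course end date.
#' @return a course list as in [detect_windowed_modality()], with
#'   `dispensings`, a tibble of the retained deliveries (`date`,
#'   `molecule` over `tamoxifen`/`aromatase_inhibitor`/`gnrh_agonist`).
#' @export
detect_endocrine_therapy <- function(events, index_date, ct_course = NULL,
                                     dictionary = default_code_dictionary(),
                                     lookback_days = 250L, pack_days = 30L) {
  index_date <- as_date_safe(index_date)
  keys <- event_keys(events)
  dates <- as.Date(character())
  mols <- character()
  for (set in ET_MOLECULE_SET_NAMES) {
    sel <- keys %in% dictionary[[set]]
    if (any(sel)) {
      dates <- c(dates, events$event_date[sel])
      mols <- c(mols, rep(set, sum(sel)))
    }
  }
  if (!length(dates)) {
    out <- empty_course("ET")
    out$dispensings <- tibble::new_tibble(
      list(date = as.Date(character()), molecule = character()), nrow = 0L)
    return(out)
  }
  o <- order(dates)
  disp <- tibble::new_tibble(list(date = dates[o], molecule = mols[o]),
                             nrow = length(o))

  # fertility-preservation exclusion
  has_tam_ai <- any(disp$molecule %in% c("tamoxifen",
                                         "aromatase_inhibitor"))
  if (!has_tam_ai && !is.null(ct_course) && isTRUE(ct_course$received)) {
    ct_start <- ct_course$start_date
    fert <- disp$molecule == "gnrh_agonist" &
      disp$date >= ct_start - 30L & disp$date < ct_start
    disp <- disp[!fert, , drop = FALSE]
  }

  in_window <- disp$date >= index_date - lookback_days
  if (!any(in_window)) {
    out <- empty_course("ET")
    out$dispensings <- disp[0, ]
    return(out)
  }
  dates <- disp$date[in_window]
  list(modality = "ET", received = TRUE,
       setting = assign_setting(dates, index_date, "ET"),
       start_date = min(dates), end_date = max(dates) + pack_days,
       regimen = NA_character_, dispensings = disp)
}

#' Classify the endocrine-therapy regimen
#'
#' Seven categories from the molecules delivered over the whole study
#' period. "Followed by" requires a single switch: every delivery of the
#' first molecule precedes every delivery of the second. GnRH agonists
#' alone, three-molecule combinations, and multi-switch sequences fall in
#' `others`.
#'
#' @param dispensings tibble with columns `date` and `molecule`
#'   (`tamoxifen`, `aromatase_inhibitor`, `gnrh_agonist`).
#' @return one of `tamoxifen`, `tamoxifen_with_gnrh`, `tamoxifen_then_ai`,
#'   `ai`, `ai_with_gnrh`, `ai_then_tamoxifen`, `others`.
#' @export
classify_et_regimen <- function(dispensings) {
  stopifnot(nrow(dispensings) >= 1)
  tam <- dispensings$date[dispensings$molecule == "tamoxifen"]
  ai <- dispensings$date[dispensings$molecule == "aromatase_inhibitor"]
  gnrh <- dispensings$date[dispensings$molecule == "gnrh_agonist"]
  has_t <- length(tam) > 0
  has_a <- length(ai) > 0
  has_g <- length(gnrh) > 0
  if (has_t && has_a) {
    if (has_g) return("others")  # three ET types
    if (max(tam) < min(ai)) return("tamoxifen_then_ai")
    if (max(ai) < min(tam)) return("ai_then_tamoxifen")
    return("others")  # interleaved / multi-switch
  }
  if (has_t) return(if (has_g) "tamoxifen_with_gnrh" else "tamoxifen")
  if (has_a) return(if (has_g) "ai_with_gnrh" else "ai")
  "others"  # GnRH agonists alone
}

#' Classify the targeted-therapy regimen
#'
#' @param events one patient's event tibble.
#' @param session_dates dates of the in-window targeted-therapy sessions.
#' @param dictionary a `code_dictionary`.
#' @return `"pertuzumab+/-trastuzumab"` if any pertuzumab code appears on
#'   an in-window session date, else `"trastuzumab"`.
#' @export
classify_tt <- function(events, session_dates,
                        dictionary = default_code_dictionary()) {
  keys <- event_keys(events)
  pert <- any(events$event_date %in% session_dates &
                keys %in% code_set(dictionary, "pertuzumab"))
  if (pert) "pertuzumab+/-trastuzumab" else "trastuzumab"
}

ranges_overlap <- function(a_start, a_end, b_start, b_end) {
  !is.na(a_start) && !is.na(b_start) && a_start <= b_end && b_start <= a_end
}

#' Classify the combination of targeted therapy with systemic treatment
#'
#' Joint six-way classification from the chemotherapy regimen, the
#' date-range concurrency of the targeted-therapy and chemotherapy
#' courses (overlap of at least one day), and endocrine-therapy presence:
#' anthracycline-then-docetaxel or anthracycline-then-paclitaxel regimens
#' concurrent with TT map to classes 1-2, docetaxel-TT to class 3,
#' paclitaxel-TT without anthracyclines to class 4 (the Tolaney regimen),
#' TT with endocrine therapy and no chemotherapy to class 5, and every
#' residual combination (including unknown chemotherapy regimens) to
#' `other`.
#'
#' @param tt_course,ct_course,et_course course lists for the patient.
#' @return one of `anthracyclines/docetaxel-TT`,
#'   `anthracyclines/paclitaxel-TT`, `docetaxel-TT`,
#'   `paclitaxel-TT (Tolaney)`, `TT-ET`, `other`.
#' @export
classify_tt_combination <- function(tt_course, ct_course, et_course) {
  stopifnot(isTRUE(tt_course$received))
  if (!isTRUE(ct_course$received)) {
    return(if (isTRUE(et_course$received)) "TT-ET" else "other")
  }
  concurrent <- ranges_overlap(tt_course$start_date, tt_course$end_date,
                               ct_course$start_date, ct_course$end_date)
  if (!concurrent) return("other")
  switch(ct_course$regimen %||% "unknown",
         "anthracyclines/docetaxel" = "anthracyclines/docetaxel-TT",
         "anthracyclines/paclitaxel" = "anthracyclines/paclitaxel-TT",
         "docetaxel" = "docetaxel-TT",
         "paclitaxel" = "paclitaxel-TT (Tolaney)",
         "other")
}

# full per-patient treatment detection; events are this patient's only
detect_patient_treatments <- function(events, inclusion_date,
                                      dictionary, windows = treatment_windows(),
                                      merge_gap = 7L, pack_days = 30L) {
  idx <- find_index_surgery(events, inclusion_date, dictionary)
  index_date <- idx$index_date
  bins <- bin_surgery(idx$surgeries)

  rt <- detect_windowed_modality(
    events, index_date, windows$rt,
    code_set(dictionary, "radiotherapy"), "RT")
  ct <- detect_windowed_modality(
    events, index_date, windows$ct,
    code_set(dictionary, "ct_session"), "CT")
  tt <- detect_windowed_modality(
    events, index_date, windows$tt,
    c(code_set(dictionary, "trastuzumab"),
      code_set(dictionary, "pertuzumab")), "TT")

  if (ct$received) {
    ct$regimen <- classify_ct_regimen(events, ct$session_dates, dictionary)
    ct$cycles <- count_cycles(ct$session_dates, index_date, merge_gap)
  }
  et <- detect_endocrine_therapy(events, index_date, ct, dictionary,
                                 lookback_days = abs(windows$ct[1]),
                                 pack_days = pack_days)
  if (et$received) et$regimen <- classify_et_regimen(et$dispensings)
  if (tt$received) {
    tt$regimen <- classify_tt(events, tt$session_dates, dictionary)
    tt$combination <- classify_tt_combination(tt, ct, et)
  }

  list(index_date = index_date, surgery = bins,
       rt = rt, ct = ct, et = et, tt = tt)
}

# column accumulator for the tidy treatments table (one tibble at the end:
# per-patient tibble construction dominates runtime otherwise)
new_course_acc <- function(n_rows) {
  list(patient_id = character(n_rows), modality = character(n_rows),
       received = logical(n_rows), setting = character(n_rows),
       start_date = rep(NA_real_, n_rows), end_date = rep(NA_real_, n_rows),
       regimen = rep(NA_character_, n_rows),
       combination = rep(NA_character_, n_rows),
       cycles_neoadjuvant = rep(NA_integer_, n_rows),
       cycles_adjuvant = rep(NA_integer_, n_rows))
}

acc_set <- function(acc, j, patient_id, course) {
  cyc <- course$cycles %||% list()
  acc$patient_id[j] <- patient_id
  acc$modality[j] <- course$modality
  acc$received[j] <- course$received
  acc$setting[j] <- course$setting
  acc$start_date[j] <- as.numeric(course$start_date)
  acc$end_date[j] <- as.numeric(course$end_date)
  acc$regimen[j] <- course$regimen %||% NA_character_
  acc$combination[j] <- course$combination %||% NA_character_
  acc$cycles_neoadjuvant[j] <- cyc$neoadjuvant %||% NA_integer_
  acc$cycles_adjuvant[j] <- cyc$adjuvant %||% NA_integer_
  acc
}

acc_tibble <- function(acc) {
  acc$start_date <- as.Date(acc$start_date, origin = "1970-01-01")
  acc$end_date <- as.Date(acc$end_date, origin = "1970-01-01")
  tibble::new_tibble(acc, nrow = length(acc$patient_id))
}

#' Detect treatments for a set of patients
#'
#' Runs the full treatment engine (index surgery, surgery binning,
#' windowed radiotherapy/chemotherapy/targeted-therapy detection,
#' endocrine-therapy detection with the fertility-preservation rule,
#' setting assignment, regimen classification, cycle counting) for each
#' requested patient.
#'
#' @param bundle a [claims_bundle()].
#' @param patient_ids patients to process (default: all).
#' @param dictionary a `code_dictionary`.
#' @param windows a [treatment_windows()] list.
#' @param merge_gap cycle merge gap in days.
#' @param pack_days dispensing interval for the endocrine course end.
#' @return a list with `courses` (per-patient course lists, named by
#'   patient) and `treatments`, a tidy tibble with one row per
#'   (patient, modality): `received`, `setting`, `start_date`, `end_date`,
#'   `regimen`, `combination`, `cycles_neoadjuvant`, `cycles_adjuvant`.
#' @export
detect_treatments <- function(bundle,
                              patient_ids = bundle$patients$patient_id,
                              dictionary = default_code_dictionary(),
                              windows = treatment_windows(),
                              merge_gap = 7L, pack_days = 30L) {
  ev_split <- split(bundle$events,
                    factor(bundle$events$patient_id,
                           levels = patient_ids))
  incl <- bundle$patients$inclusion_date[
    match(patient_ids, bundle$patients$patient_id)]
  courses <- vector("list", length(patient_ids))
  names(courses) <- patient_ids
  acc <- new_course_acc(5L * length(patient_ids))
  for (i in seq_along(patient_ids)) {
    pid <- patient_ids[i]
    res <- detect_patient_treatments(ev_split[[i]], incl[i], dictionary,
                                     windows, merge_gap, pack_days)
    courses[[i]] <- res
    j <- 5L * (i - 1L)
    acc <- acc_set(acc, j + 1L, pid, list(
      modality = "surgery", received = TRUE, setting = "surgery",
      start_date = res$index_date, end_date = res$index_date,
      regimen = paste0(res$surgery$breast_type,
                       if (res$surgery$axillary) "+axillary" else "")))
    acc <- acc_set(acc, j + 2L, pid, res$rt)
    acc <- acc_set(acc, j + 3L, pid, res$ct)
    acc <- acc_set(acc, j + 4L, pid, res$et)
    acc <- acc_set(acc, j + 5L, pid, res$tt)
  }
  list(courses = courses, treatments = acc_tibble(acc))
}
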