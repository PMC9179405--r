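# Dating the diagnosis: first treatment date, diagnostic-procedure
# precedence (biopsy > cytology > imaging chain), and age at diagnosis.

#' Date of first breast-cancer treatment
#'
#' The earliest of the index surgery date and the start dates of the
#' neoadjuvant components present (neoadjuvant chemotherapy, endocrine
#' therapy, radiotherapy or targeted therapy).
#'
#' @param courses per-patient course list as returned by the treatment
#'   engine (elements `rt`, `ct`, `et`, `tt`).
#' @param index_date index surgery date.
#' @return a `Date`.
#' @export
first_treatment_date <- function(courses, index_date) {
  index_date <- as_date_safe(index_date)
  starts <- index_date
  for (m in c("rt", "ct", "et", "tt")) {
    co <- courses[[m]]
    if (!is.null(co) && isTRUE(co$received) &&
        co$setting %in% c("neoadjuvant", "both",
                          "neoadjuvant_then_adjuvant")) {
      starts <- c(starts, co$start_date)
    }
  }
  min(starts)
}

#' Diagnosis mode and date
#'
#' Precedence over the diagnostic procedures preceding the first
#' treatment: (a) the earliest breast core biopsy within the 12 months
#' (365 days) before first treatment sets the diagnosis; else (b) the
#' earliest fine-needle aspiration cytology in the same window; else
#' (c) starting from the breast imaging procedure closest to (and not
#' after) the first treatment, walk backwards through imaging procedures
#' while consecutive gaps are at most one month (30 days) and return the
#' earliest procedure reached; else (d) the first treatment date itself.
#'
#' @param diagnostic_events tibble with columns `date` and `category`
#'   (`"biopsy"`, `"cytology"`, `"imaging"`).
#' @param first_treatment the first-treatment date.
#' @param window_days biopsy/cytology look-back (default 365).
#' @param month_days maximal gap in the imaging chain (default 30).
#' @return list with `mode` (`biopsy`, `cytology`, `imaging_only`,
#'   `none`) and `date`.
#' @export
diagnosis_date <- function(diagnostic_events, first_treatment,
                           window_days = 365L, month_days = 30L) {
  first_treatment <- as_date_safe(first_treatment)
  ev <- diagnostic_events
  in_window <- function(cat) {
    d <- ev$date[ev$category == cat]
    d[d >= first_treatment - window_days & d <= first_treatment]
  }
  b <- in_window("biopsy")
  if (length(b)) return(list(mode = "biopsy", date = min(b)))
  cy <- in_window("cytology")
  if (length(cy)) return(list(mode = "cytology", date = min(cy)))
  img <- sort(unique(ev$date[ev$category == "imaging" &
                               ev$date <= first_treatment]))
  if (length(img)) {
    # backward chain from the imaging event closest to first treatment
    cur <- length(img)
    while (cur > 1 &&
           as.numeric(img[cur] - img[cur - 1]) <= month_days) {
      cur <- cur - 1
    }
    return(list(mode = "imaging_only", date = img[cur]))
  }
  list(mode = "none", date = first_treatment)
}

#' Age at diagnosis
#'
#' Rounded (half-up) difference in years between the diagnosis date and
#' the birth date, on the 365.25-day year.
#'
#' @param birth_date,diagnosis_date calendar dates (vectors recycle).
#' @return integer years.
#' @export
#' @examples
#' age_at_diagnosis("1960-01-01", "2020-01-01")
age_at_diagnosis <- function(birth_date, diagnosis_date) {
  d <- as.numeric(as_date_safe(diagnosis_date) - as_date_safe(birth_date))
  if (any(d < 0)) abort_ctx("diagnosis before birth", "date_error")
  as.integer(round_half_up(d / 365.25))
}

# per-patient diagnostic events, categorised
diagnostic_events_for <- function(events, dictionary) {
  keys <- event_keys(events)
  sets <- c(breast_biopsy = "biopsy", breast_cytology = "cytology",
            breast_imaging = "imaging")
  dates <- as.Date(character())
  cats <- character()
  for (set in names(sets)) {
    sel <- keys %in% dictionary[[set]]
    if (any(sel)) {
      dates <- c(dates, events$event_date[sel])
      cats <- c(cats, rep(sets[[set]], sum(sel)))
    }
  }
  tibble::new_tibble(list(date = dates, category = cats),
                     nrow = length(dates))
}
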