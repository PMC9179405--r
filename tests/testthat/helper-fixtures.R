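# In-code fixture builders: tiny patients/event tables assembled from the
# default code dictionary's placeholder codes.

DICT <- default_code_dictionary()

key1 <- function(set) code_set(DICT, set)[1]

pat_tbl <- function(id = "p1", sex = "female", birth = "1960-01-01",
                    plan = "general", vital = "alive", death = NA,
                    inclusion = "2013-03-01") {
  tibble::tibble(patient_id = id, sex = sex, birth_date = as.Date(birth),
                 insurance_plan = plan, vital_status = vital,
                 death_date = as.Date(death),
                 inclusion_date = as.Date(inclusion))
}

ev_tbl <- function(id, date, key, context = "hospital") {
  parts <- strsplit(key, ":", fixed = TRUE)
  tibble::tibble(patient_id = id, event_date = as.Date(date),
                 code_system = vapply(parts, `[`, "", 1),
                 code = vapply(parts, `[`, "", 2),
                 care_context = context)
}

# one clean patient: BC code at inclusion, surgery `surg_delay` days later
clean_bundle <- function(id = "p1", inclusion = "2013-03-01",
                         surg_delay = 30, extra_events = NULL, ...) {
  inclusion <- as.Date(inclusion)
  ev <- dplyr::bind_rows(
    ev_tbl(id, inclusion, key1("bc_diagnosis")),
    ev_tbl(id, inclusion + surg_delay,
           key1("surgery_partial_without_axillary")),
    extra_events)
  claims_bundle(pat_tbl(id = id, inclusion = inclusion, ...), ev)
}

# events for one patient given day offsets from an index date
offset_events <- function(id, index_date, offsets, set,
                          context = "hospital") {
  ev_tbl(id, as.Date(index_date) + offsets,
         rep(key1(set), length(offsets)), context)
}
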