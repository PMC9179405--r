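# Treatment-based phenotyping: tumour subtype inferred from treatment
# exposure, nodal status from node-disease codes around surgery, canonical
# treatment sequences and main care pathways.

AGE_CLASS_BREAKS <- c(0, 30, 40, 50, 60, 70, 80, Inf)
AGE_CLASS_LABELS <- c("0-30", "30-40", "40-50", "50-60", "60-70", "70-80",
                      "80+")

#' Age class
#'
#' Seven canonical age bins, right-open except the last: `[0,30)`,
#' `[30,40)`, ..., `[70,80)`, `80+`.
#'
#' @param age integer or numeric ages in years.
#' @return factor with the seven age-class labels.
#' @export
age_class <- function(age) {
  cut(age, breaks = AGE_CLASS_BREAKS, labels = AGE_CLASS_LABELS,
      right = FALSE)
}

#' Infer tumour subtype from treatments received
#'
#' Claims carry no receptor status, so the subtype is a treatment proxy:
#' any anti-HER2 targeted therapy makes the tumour HER2+, split into
#' HER2+/HR+ vs HER2+/HR- by endocrine-therapy exposure; endocrine therapy
#' without targeted therapy is luminal; chemotherapy without endocrine or
#' targeted therapy is triple-negative (TNBC); patients treated by surgery
#' with or without radiotherapy only are `undefined`. Total on the 8-cell
#' truth table; vectorized.
#'
#' @param ct,et,tt logical vectors: modality received.
#' @return character vector over `luminal`, `TNBC`, `HER2+/HR+`,
#'   `HER2+/HR-`, `undefined`.
#' @export
#' @examples
#' infer_subtype(ct = TRUE, et = FALSE, tt = FALSE)   # TNBC
#' infer_subtype(ct = FALSE, et = TRUE, tt = TRUE)    # HER2+/HR+
infer_subtype <- function(ct, et, tt) {
  ifelse(tt, ifelse(et, "HER2+/HR+", "HER2+/HR-"),
         ifelse(et, "luminal", ifelse(ct, "TNBC", "undefined")))
}

#' Nodal status
#'
#' Node-positive iff at least one node-disease diagnosis code falls in the
#' closed window around the index surgery (default `[-250, +180]` days).
#'
#' @param events one patient's event tibble.
#' @param index_date index surgery date.
#' @param dictionary a `code_dictionary`.
#' @param window closed day-offset window.
#' @return logical.
#' @export
nodal_status <- function(events, index_date,
                         dictionary = default_code_dictionary(),
                         window = c(-250L, 180L)) {
  dates <- events$event_date[
    event_keys(events) %in% code_set(dictionary, "node_disease")]
  off <- as.numeric(dates - as_date_safe(index_date))
  any(off >= window[1] & off <= window[2])
}

#' Assign the main care pathway
#'
#' Precedence over the neoadjuvant components: neoadjuvant chemotherapy
#' (NAC) dominates neoadjuvant radiotherapy (NRT), which dominates
#' neoadjuvant endocrine therapy (NET), irrespective of the other
#' neoadjuvant treatments present. Patients with no neoadjuvant component
#' split into surgery followed by chemotherapy vs surgery without
#' chemotherapy. NRT-only is kept as an explicit (rare) fifth class.
#' Vectorized over setting labels.
#'
#' @param ct_setting,rt_setting,et_setting setting labels (`none` when the
#'   modality was not received).
#' @return character vector over `NAC`, `NRT`, `NET`, `surgery_then_CT`,
#'   `surgery_no_CT`.
#' @export
assign_main_pathway <- function(ct_setting, rt_setting, et_setting) {
  ifelse(ct_setting %in% c("neoadjuvant", "both"), "NAC",
  ifelse(rt_setting %in% c("neoadjuvant", "both"), "NRT",
  ifelse(et_setting == "neoadjuvant_then_adjuvant", "NET",
  ifelse(ct_setting == "adjuvant", "surgery_then_CT", "surgery_no_CT"))))
}

SEQUENCE_SLOTS <- c("NAC", "NTT", "NRT", "NET", "surgery", "adjCT",
                    "adjTT", "adjRT", "adjET")

#' Derive the canonical treatment sequence
#'
#' Nine ordered slots: NAC, NTT, NRT, NET, surgery, adjuvant CT, adjuvant
#' TT, adjuvant RT, adjuvant ET. Radiotherapy/chemotherapy in the `both`
#' setting fill both their slots; the continuation of neoadjuvant
#' endocrine or targeted therapy after surgery is not counted as adjuvant,
#' so a `neoadjuvant_then_adjuvant` course fills only its neoadjuvant
#' slot.
#'
#' @param courses per-patient course list (elements `rt`, `ct`, `et`,
#'   `tt`).
#' @return character vector of the slots present, in canonical order.
#' @export
derive_sequence <- function(courses) {
  setting_of <- function(m) {
    co <- courses[[m]]
    if (is.null(co) || !isTRUE(co$received)) "none" else co$setting
  }
  ct <- setting_of("ct")
  rt <- setting_of("rt")
  et <- setting_of("et")
  tt <- setting_of("tt")
  present <- c(
    NAC = ct %in% c("neoadjuvant", "both"),
    NTT = tt == "neoadjuvant_then_adjuvant",
    NRT = rt %in% c("neoadjuvant", "both"),
    NET = et == "neoadjuvant_then_adjuvant",
    surgery = TRUE,
    adjCT = ct %in% c("adjuvant", "both"),
    adjTT = tt == "adjuvant",
    adjRT = rt %in% c("adjuvant", "both"),
    adjET = et == "adjuvant")
  SEQUENCE_SLOTS[present]
}

#' Build the cohort from a claims bundle
#'
#' End-to-end construction: applies the ten selection filters, runs the
#' treatment engine on every included patient, dates the diagnosis,
#' computes age (class), subtype, nodal status, treatment sequence, main
#' pathway, and overall-survival time (months from index surgery to death
#' or the cutoff, censored at the cutoff).
#'
#' @param bundle a [claims_bundle()].
#' @param dictionary a `code_dictionary`.
#' @param selection a [selection_config()].
#' @param windows a [treatment_windows()] list.
#' @param cutoff_date administrative censoring date for overall survival.
#' @param merge_gap,pack_days,month_days tunable day constants (cycle
#'   merge gap, dispensing interval, imaging-chain gap).
#' @return a list of class `cohort_build`: `cohort` (tibble, one row per
#'   included patient), `treatments` (tidy course table), `attrition`
#'   (the filter report), and `included` ids.
#' @export
#' @examples
#' sim <- simulate_claims(sim_preset("clean_small", n_patients = 40, seed = 2))
#' cb <- build_cohort(sim$bundle)
#' cb$cohort[, c("patient_id", "subtype", "main_pathway")]
build_cohort <- function(bundle,
                         dictionary = default_code_dictionary(),
                         selection = selection_config(),
                         windows = treatment_windows(),
                         cutoff_date = as.Date("2019-03-01"),
                         merge_gap = 7L, pack_days = 30L,
                         month_days = 30L) {
  sel <- apply_filters(bundle, selection, dictionary)
  det <- detect_treatments(bundle, sel$included, dictionary, windows,
                           merge_gap, pack_days)
  p <- bundle$patients
  ev_split <- split(bundle$events,
                    factor(bundle$events$patient_id,
                           levels = sel$included))
  n_inc <- length(sel$included)
  col <- list(
    patient_id = character(n_inc), index_date = rep(NA_real_, n_inc),
    first_treatment_date = rep(NA_real_, n_inc),
    diagnosis_mode = character(n_inc),
    diagnosis_date = rep(NA_real_, n_inc),
    age_at_diagnosis = integer(n_inc), age_class = character(n_inc),
    subtype = character(n_inc), node_positive = logical(n_inc),
    surgery_breast_type = character(n_inc),
    surgery_axillary = logical(n_inc), rt_setting = character(n_inc),
    ct_setting = character(n_inc), et_setting = character(n_inc),
    tt_setting = character(n_inc), sequence = character(n_inc),
    main_pathway = character(n_inc),
    survival_time_months = numeric(n_inc), event = logical(n_inc))
  pat_row <- match(sel$included, p$patient_id)
  for (i in seq_len(n_inc)) {
    pid <- sel$included[i]
    res <- det$courses[[pid]]
    events <- ev_split[[i]]
    birth <- p$birth_date[pat_row[i]]
    death <- p$death_date[pat_row[i]]
    ft <- first_treatment_date(res, res$index_date)
    dx <- diagnosis_date(diagnostic_events_for(events, dictionary), ft,
                         month_days = month_days)
    age <- age_at_diagnosis(birth, dx$date)
    os_end <- min(death, cutoff_date, na.rm = TRUE)
    col$patient_id[i] <- pid
    col$index_date[i] <- as.numeric(res$index_date)
    col$first_treatment_date[i] <- as.numeric(ft)
    col$diagnosis_mode[i] <- dx$mode
    col$diagnosis_date[i] <- as.numeric(dx$date)
    col$age_at_diagnosis[i] <- age
    col$age_class[i] <- as.character(age_class(age))
    col$subtype[i] <- infer_subtype(res$ct$received, res$et$received,
                                    res$tt$received)
    col$node_positive[i] <- nodal_status(events, res$index_date,
                                         dictionary, windows$node)
    col$surgery_breast_type[i] <- res$surgery$breast_type
    col$surgery_axillary[i] <- res$surgery$axillary
    col$rt_setting[i] <- res$rt$setting
    col$ct_setting[i] <- res$ct$setting
    col$et_setting[i] <- res$et$setting
    col$tt_setting[i] <- res$tt$setting
    col$sequence[i] <- paste(derive_sequence(res), collapse = ">")
    col$main_pathway[i] <- assign_main_pathway(res$ct$setting,
                                               res$rt$setting,
                                               res$et$setting)
    col$survival_time_months[i] <- days_to_months(os_end - res$index_date)
    col$event[i] <- !is.na(death) && death <= cutoff_date
  }
  for (dcol in c("index_date", "first_treatment_date", "diagnosis_date")) {
    col[[dcol]] <- as.Date(col[[dcol]], origin = "1970-01-01")
  }
  structure(list(cohort = tibble::new_tibble(col, nrow = n_inc),
                 treatments = det$treatments,
                 attrition = sel$attrition,
                 included = sel$included,
                 cutoff_date = cutoff_date),
            class = "cohort_build")
}

#' @export
print.cohort_build <- function(x, ...) {
  cat("<cohort_build> ", nrow(x$cohort), " included patients (",
      x$attrition$n_before[1], " screened)\n", sep = "")
  pw <- table(x$cohort$main_pathway)
  cat("  pathways: ",
      paste(names(pw), pw, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
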