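# Synthetic claims generator. Emits a claims bundle plus a per-patient
# ground-truth table so that every downstream stage (filters, treatment
# detection, subtype and pathway inference, survival) can be tested against
# known labels without access to restricted national claims data.
#
# Treatments are generated from the subtype via the inverse of the
# treatment-based subtype inference map, so that on noise-free draws the
# pipeline must recover subtype, pathway and setting labels exactly.

SUBTYPES <- c("luminal", "TNBC", "HER2+/HR+", "HER2+/HR-", "undefined")
PATHWAYS <- c("surgery_no_CT", "surgery_then_CT", "NAC", "NRT", "NET")
CONTAMINATION_REASONS <- c("male", "under_18", "non_general_plan",
                           "no_surgery", "other_cancer", "prior_bc",
                           "metastatic", "corrupt")

# Which selection filter catches each injected contaminant class.
#' Map contamination reasons to selection filters
#'
#' Returns the filter (by name and position in the ten-filter battery) at
#' which each class of injected contaminant patient is expected to be
#' excluded. Used to check filter attrition against generator labels.
#'
#' @return tibble with columns `exclusion_reason`, `filter_index`,
#'   `filter_name`.
#' @export
contaminant_filter_map <- function() {
  tibble::tibble(
    exclusion_reason = CONTAMINATION_REASONS,
    filter_index = c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
    filter_name = FILTER_NAMES[c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L)]
  )
}

default_pathway_probs <- function() {
  list(
    "luminal"   = c(surgery_no_CT = 0.630, surgery_then_CT = 0.299,
                    NAC = 0.056, NRT = 0.001, NET = 0.014),
    "TNBC"      = c(surgery_no_CT = 0, surgery_then_CT = 0.70,
                    NAC = 0.30, NRT = 0, NET = 0),
    "HER2+/HR+" = c(surgery_no_CT = 0.05, surgery_then_CT = 0.60,
                    NAC = 0.35, NRT = 0, NET = 0),
    "HER2+/HR-" = c(surgery_no_CT = 0, surgery_then_CT = 0.62,
                    NAC = 0.38, NRT = 0, NET = 0),
    "undefined" = c(surgery_no_CT = 1, surgery_then_CT = 0,
                    NAC = 0, NRT = 0, NET = 0)
  )
}

default_timing <- function() {
  list(
    surgery_delay = c(15L, 60L),    # days from inclusion to index surgery
    nac_start = c(-180L, -140L),    # NAC start offset from surgery
    adj_ct_start = c(25L, 60L),
    ct_cycle_gap = 21L, ct_cycles = 6L,
    rt_adj_start = c(60L, 180L), rt_sessions = 15L,
    nrt_start = c(-140L, -90L),
    et_adj_start = c(60L, 120L), net_start = c(-220L, -160L),
    et_dispense_gap = 30L, et_duration_months = 60L,
    tt_cycles = 18L,
    biopsy_offset = c(-60L, -15L),  # from first treatment
    imaging_anchor_offset = c(-15L, -5L),
    imaging_gap = c(10L, 30L)
  )
}

#' Simulation configuration
#'
#' Assembles and validates the generative model for a synthetic claims
#' bundle: cohort size, an age-at-diagnosis Gaussian mixture, subtype
#' shares, pathway shares conditional on subtype, per-reason contamination
#' rates (each contaminant class carries exactly the claim pattern that
#' trips one selection filter), modality timing relative to the index
#' surgery, and per-subtype annual death hazards.
#'
#' @param n_patients number of patients to draw.
#' @param seed integer seed; fixes the full output bit-for-bit.
#' @param age_mixture data frame with columns `weight`, `mean`, `sd` for a
#'   Gaussian mixture of age at diagnosis in years (weights sum to 1).
#' @param subtype_probs named probabilities over
#'   `luminal`, `TNBC`, `HER2+/HR+`, `HER2+/HR-`, `undefined`.
#' @param pathway_probs named list (one element per subtype) of
#'   probabilities over `surgery_no_CT`, `surgery_then_CT`, `NAC`, `NRT`,
#'   `NET`. Combinations incompatible with the subtype's treatment pattern
#'   must have probability 0.
#' @param contamination_rates named rates in `[0,1]` (summing with the
#'   included share to 1) over `male`, `under_18`, `non_general_plan`,
#'   `no_surgery`, `other_cancer`, `prior_bc`, `metastatic`, `corrupt`.
#' @param timing list of day-offset ranges and cadences; see
#'   `cohortpath:::default_timing()` for the fields and defaults.
#' @param annual_death_hazard named per-subtype annual death rates.
#' @param rt_prob probability of (adjuvant) radiotherapy for non-NRT
#'   pathways.
#' @param ct_both_prob probability that a NAC patient also receives an
#'   adjuvant chemotherapy block (setting `both`).
#' @param node_positive_probs named per-subtype nodal-involvement rates.
#' @param ct_regimen_probs,et_regimen_probs named regimen draws.
#' @param pertuzumab_prob share of targeted-therapy courses including
#'   pertuzumab.
#' @param diag_mode_probs probabilities over diagnosis modes
#'   `biopsy`, `cytology`, `imaging_only`, `none`.
#' @param fertility_decoy_prob probability that a chemotherapy patient
#'   without endocrine therapy carries a single GnRH-agonist delivery just
#'   before chemotherapy start (a fertility-preservation decoy the
#'   endocrine-therapy detector must discard).
#' @param cutoff_date administrative censoring date.
#' @param incidence_window two dates bounding inclusion.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 1000,
                       seed = 1L,
                       age_mixture = data.frame(
                         weight = c(0.5, 0.5),
                         mean = c(50.3, 65.0),
                         sd = c(5.0, 5.0)),
                       subtype_probs = c(
                         "luminal" = 0.6504, "TNBC" = 0.0770,
                         "HER2+/HR+" = 0.0532, "HER2+/HR-" = 0.0304,
                         "undefined" = 0.1890),
                       pathway_probs = default_pathway_probs(),
                       contamination_rates = c(
                         male = 0, under_18 = 0, non_general_plan = 0,
                         no_surgery = 0, other_cancer = 0, prior_bc = 0,
                         metastatic = 0, corrupt = 0),
                       timing = list(),
                       annual_death_hazard = c(
                         "luminal" = 0.010, "TNBC" = 0.030,
                         "HER2+/HR+" = 0.015, "HER2+/HR-" = 0.020,
                         "undefined" = 0.015),
                       rt_prob = 0.853,
                       ct_both_prob = 0.02,
                       node_positive_probs = c(
                         "luminal" = 0.215, "TNBC" = 0.270,
                         "HER2+/HR+" = 0.280, "HER2+/HR-" = 0.301,
                         "undefined" = 0.100),
                       ct_regimen_probs = c(
                         anthracyclines = 0.008,
                         "anthracyclines/docetaxel" = 0.151,
                         "anthracyclines/paclitaxel" = 0.235,
                         docetaxel = 0.054, paclitaxel = 0.031,
                         other = 0.070, unknown = 0.451),
                       et_regimen_probs = c(
                         ai = 0.620, tamoxifen = 0.212,
                         tamoxifen_then_ai = 0.062,
                         ai_then_tamoxifen = 0.048,
                         tamoxifen_with_gnrh = 0.006,
                         ai_with_gnrh = 0.004, others = 0.048),
                       pertuzumab_prob = 0.022,
                       diag_mode_probs = c(
                         biopsy = 0.913, cytology = 0.020,
                         imaging_only = 0.056, none = 0.011),
                       fertility_decoy_prob = 0,
                       cutoff_date = as.Date("2019-03-01"),
                       incidence_window = as.Date(c("2011-01-01",
                                                    "2017-12-31"))) {
  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    age_mixture = as.data.frame(age_mixture),
    subtype_probs = subtype_probs, pathway_probs = pathway_probs,
    contamination_rates = contamination_rates,
    timing = utils::modifyList(default_timing(), timing),
    annual_death_hazard = annual_death_hazard,
    rt_prob = rt_prob, ct_both_prob = ct_both_prob,
    node_positive_probs = node_positive_probs,
    ct_regimen_probs = ct_regimen_probs,
    et_regimen_probs = et_regimen_probs,
    pertuzumab_prob = pertuzumab_prob,
    diag_mode_probs = diag_mode_probs,
    fertility_decoy_prob = fertility_decoy_prob,
    cutoff_date = as.Date(cutoff_date),
    incidence_window = as.Date(incidence_window)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_probs <- function(p, what, names_expected = NULL) {
    if (!is.null(names_expected) && !setequal(names(p), names_expected)) {
      abort_ctx(paste0(what, " must be named over: ",
                       paste(names_expected, collapse = ", ")),
                "config_error")
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort_ctx(paste0(what, " must be a probability vector summing to 1"),
                "config_error")
    }
  }
  if (cfg$n_patients < 1) abort_ctx("n_patients must be >= 1", "config_error")
  check_probs(cfg$subtype_probs, "subtype_probs", SUBTYPES)
  check_probs(cfg$diag_mode_probs, "diag_mode_probs",
              c("biopsy", "cytology", "imaging_only", "none"))
  check_probs(cfg$ct_regimen_probs, "ct_regimen_probs")
  check_probs(cfg$et_regimen_probs, "et_regimen_probs")
  check_probs(cfg$age_mixture$weight, "age_mixture weights")
  for (s in SUBTYPES) {
    check_probs(cfg$pathway_probs[[s]], paste0("pathway_probs[", s, "]"),
                PATHWAYS)
  }
  # structural consistency: a pathway implying treatments the subtype
  # forbids (or vice versa) must have probability zero
  if (cfg$pathway_probs[["undefined"]]["surgery_no_CT"] != 1) {
    abort_ctx("undefined subtype admits only the surgery_no_CT pathway",
              "config_error")
  }
  for (s in c("TNBC", "HER2+/HR-")) {
    if (sum(cfg$pathway_probs[[s]][c("surgery_no_CT", "NET", "NRT")]) > 0) {
      abort_ctx(paste0(s, " requires chemotherapy: only surgery_then_CT ",
                       "and NAC pathways are admissible"), "config_error")
    }
  }
  if (sum(cfg$pathway_probs[["HER2+/HR+"]][c("NET", "NRT")]) > 0) {
    abort_ctx("HER2+/HR+ admits surgery_no_CT (TT with ET), ",
              "config_error")
  }
  r <- cfg$contamination_rates
  if (!setequal(names(r), CONTAMINATION_REASONS)) {
    abort_ctx(paste0("contamination_rates must be named over: ",
                     paste(CONTAMINATION_REASONS, collapse = ", ")),
              "config_error")
  }
  if (any(r < 0 | r > 1) || sum(r) > 1) {
    abort_ctx("contamination_rates must lie in [0,1] and sum to at most 1",
              "config_error")
  }
  invisible(TRUE)
}

#' Named simulation presets
#'
#' * `clean_small`: 200 patients, zero contamination — every patient passes
#'   all ten filters.
#' * `realistic`: bimodal age mixture with modes at 50.3 and 65.0 years,
#'   subtype mix luminal/TNBC/HER2+ = 0.802/0.095/0.103 among defined
#'   subtypes (HER2+ split 0.637/0.363 into HR+/HR-) with an undefined
#'   share of 0.189, plus moderate contamination including a 4.5%
#'   metastatic-suspicion rate.
#' * `contaminated`: every contaminant class injected at a substantial
#'   rate, for exercising the filter battery.
#' * `survival_demo`: clean cohort with inflated death hazards, for
#'   exercising the survival estimators.
#'
#' @param name one of `"clean_small"`, `"realistic"`, `"contaminated"`,
#'   `"survival_demo"`.
#' @param ... overrides forwarded to [sim_config()] (e.g. `n_patients`,
#'   `seed`).
#' @return a `sim_config`.
#' @export
#' @examples
#' cfg <- sim_preset("clean_small", seed = 7)
#' cfg$n_patients
sim_preset <- function(name, ...) {
  dots <- list(...)
  base <- switch(
    name,
    clean_small = list(n_patients = 200),
    realistic = list(
      n_patients = 5000,
      contamination_rates = c(
        male = 0.010, under_18 = 0.002, non_general_plan = 0.060,
        no_surgery = 0.040, other_cancer = 0.015, prior_bc = 0.015,
        metastatic = 0.045, corrupt = 0.005)),
    contaminated = list(
      n_patients = 5000,
      contamination_rates = c(
        male = 0.030, under_18 = 0.020, non_general_plan = 0.030,
        no_surgery = 0.030, other_cancer = 0.030, prior_bc = 0.030,
        metastatic = 0.045, corrupt = 0.020)),
    survival_demo = list(
      n_patients = 1000,
      annual_death_hazard = c(
        "luminal" = 0.05, "TNBC" = 0.15, "HER2+/HR+" = 0.08,
        "HER2+/HR-" = 0.10, "undefined" = 0.06)),
    abort_ctx(paste0("unknown preset: ", name), "config_error")
  )
  do.call(sim_config, utils::modifyList(base, dots))
}

# uniform integer draw in [lo, hi] per element, vectorized
runif_int <- function(n, range) {
  as.integer(floor(stats::runif(n, range[1], range[2] + 1L)))
}

draw_ages <- function(n, mixture) {
  comp <- sample.int(nrow(mixture), n, replace = TRUE,
                     prob = mixture$weight)
  age <- stats::rnorm(n, mixture$mean[comp], mixture$sd[comp])
  # included patients must clear the adult filter; redraw implausible tails
  while (any(bad <- age < 19 | age > 105)) {
    k <- which(bad)
    comp <- sample.int(nrow(mixture), length(k), replace = TRUE,
                       prob = mixture$weight)
    age[k] <- stats::rnorm(length(k), mixture$mean[comp], mixture$sd[comp])
  }
  age
}

sample_factor <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

#' Generate a synthetic claims bundle with ground truth
#'
#' Draws a cohort under `config`: ages from the Gaussian mixture, subtype
#' then pathway, treatment courses generated deterministically from the
#' subtype (the inverse of the treatment-based subtype inference), event
#' timelines placed in the correct temporal windows around the index
#' surgery, death times from per-subtype exponential hazards censored at
#' the cutoff, and contaminant patients mutated to carry exactly the claim
#' pattern their selection filter targets.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_claims` with elements `bundle`
#'   (a [claims_bundle()]) and `ground_truth` (a tibble with one row per
#'   patient: `exclusion_reason` of `"included"` or one contaminant class,
#'   and for included patients the true subtype, pathway, index date,
#'   per-modality received/setting/regimen labels, nodal status, diagnosis
#'   mode and date, age, and death information).
#' @export
#' @examples
#' sim <- simulate_claims(sim_preset("clean_small", n_patients = 50, seed = 1))
#' sim$bundle
#' dplyr::count(sim$ground_truth, true_subtype)
simulate_claims <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n <- config$n_patients
  tm <- config$timing
  dict <- default_code_dictionary()
  pick1 <- function(set_name) code_set(dict, set_name)[1]
  split_key <- function(keys) {
    m <- regmatches(keys, regexpr(":", keys), invert = TRUE)
    list(system = vapply(m, `[`, "", 1), code = vapply(m, `[`, "", 2))
  }

  patient_id <- sprintf("s%d_p%05d", config$seed, seq_len(n))

  reasons <- c(config$contamination_rates,
               included = 1 - sum(config$contamination_rates))
  exclusion_reason <- sample_factor(n, reasons)

  subtype <- sample_factor(n, config$subtype_probs)
  pathway <- character(n)
  for (s in SUBTYPES) {
    idx <- which(subtype == s)
    if (length(idx)) pathway[idx] <- sample_factor(length(idx),
                                                   config$pathway_probs[[s]])
  }

  age <- draw_ages(n, config$age_mixture)
  window_days <- as.integer(config$incidence_window[2] -
                              config$incidence_window[1])
  inclusion_date <- config$incidence_window[1] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L
  index_date <- inclusion_date + runif_int(n, tm$surgery_delay)

  # modality flags from subtype x pathway (inverse of the inference map)
  ct <- pathway %in% c("surgery_then_CT", "NAC")
  et <- subtype %in% c("luminal", "HER2+/HR+")
  tt <- subtype %in% c("HER2+/HR+", "HER2+/HR-")
  ct_setting <- ifelse(!ct, "none",
                       ifelse(pathway == "NAC", "neoadjuvant", "adjuvant"))
  both_ct <- ct_setting == "neoadjuvant" &
    stats::runif(n) < config$ct_both_prob
  ct_setting[both_ct] <- "both"
  rt <- pathway == "NRT" | stats::runif(n) < config$rt_prob
  rt_setting <- ifelse(!rt, "none",
                       ifelse(pathway == "NRT", "neoadjuvant", "adjuvant"))
  et_setting <- ifelse(!et, "none",
                       ifelse(pathway == "NET", "neoadjuvant_then_adjuvant",
                              "adjuvant"))
  tt_setting <- ifelse(!tt, "none",
                       ifelse(pathway == "NAC", "neoadjuvant_then_adjuvant",
                              "adjuvant"))

  ct_regimen <- ifelse(ct, sample_factor(n, config$ct_regimen_probs),
                       NA_character_)
  et_regimen <- ifelse(et, sample_factor(n, config$et_regimen_probs),
                       NA_character_)
  tt_regimen <- ifelse(tt,
                       ifelse(stats::runif(n) < config$pertuzumab_prob,
                              "pertuzumab+/-trastuzumab", "trastuzumab"),
                       NA_character_)
  node_positive <- stats::runif(n) <
    config$node_positive_probs[subtype]

  # surgery category
  mastectomy <- stats::runif(n) < 0.264
  axillary <- stats::runif(n) < 0.838
  surgery_set <- ifelse(
    mastectomy,
    ifelse(axillary, "surgery_total_with_axillary",
           "surgery_total_without_axillary"),
    ifelse(axillary, "surgery_partial_with_axillary",
           "surgery_partial_without_axillary"))

  # per-patient offsets (days relative to index surgery)
  nac_start <- runif_int(n, tm$nac_start)
  adj_ct_start <- runif_int(n, tm$adj_ct_start)
  rt_start <- ifelse(pathway == "NRT", runif_int(n, tm$nrt_start),
                     runif_int(n, tm$rt_adj_start))
  et_start <- ifelse(pathway == "NET", runif_int(n, tm$net_start),
                     runif_int(n, tm$et_adj_start))
  tt_start <- ifelse(pathway == "NAC", nac_start,
                     ifelse(ct, adj_ct_start, 30L))

  neo_ct_start <- ifelse(ct_setting %in% c("neoadjuvant", "both"),
                         nac_start, NA_integer_)
  first_treatment_off <- pmin(
    0L,
    ifelse(!is.na(neo_ct_start), neo_ct_start, 0L),
    ifelse(rt_setting == "neoadjuvant", rt_start, 0L),
    ifelse(et_setting == "neoadjuvant_then_adjuvant", et_start, 0L),
    ifelse(tt_setting == "neoadjuvant_then_adjuvant", tt_start, 0L))
  first_treatment_date <- index_date + first_treatment_off

  # diagnostic procedures and true diagnosis date
  diag_mode <- sample_factor(n, config$diag_mode_probs)
  biopsy_off <- runif_int(n, tm$biopsy_offset)
  img_anchor_off <- runif_int(n, tm$imaging_anchor_offset)
  img_gap <- runif_int(n, tm$imaging_gap)
  diagnosis_date <- as.Date(ifelse(
    diag_mode %in% c("biopsy", "cytology"),
    first_treatment_date + biopsy_off,
    ifelse(diag_mode == "imaging_only",
           first_treatment_date + img_anchor_off - img_gap,
           first_treatment_date)), origin = "1970-01-01")
  birth_date <- diagnosis_date - as.integer(round(age * 365.25))

  # --- event blocks (vectorized by modality) ---
  blocks <- list()
  add_block <- function(pid, date, key, context) {
    sk <- split_key(key)
    blocks[[length(blocks) + 1]] <<- tibble::tibble(
      patient_id = pid, event_date = as.Date(date, origin = "1970-01-01"),
      code_system = sk$system, code = sk$code, care_context = context)
  }

  add_block(patient_id, inclusion_date,
            rep(pick1("bc_diagnosis"), n), "hospital")
  surg_key <- unname(vapply(SURGERY_SET_NAMES, pick1, "")[surgery_set])
  add_block(patient_id, index_date, surg_key, "hospital")
  i_node <- which(node_positive)
  if (length(i_node)) {
    add_block(patient_id[i_node], index_date[i_node] + 5L,
              rep(pick1("node_disease"), length(i_node)), "hospital")
  }

  session_block <- function(idx, start_off, n_sessions, gap, set_name,
                            context = "hospital") {
    if (!length(idx)) return(invisible(NULL))
    k <- rep(idx, each = n_sessions)
    off <- start_off[k] + gap * rep(seq_len(n_sessions) - 1L, length(idx))
    add_block(patient_id[k], index_date[k] + off,
              rep(pick1(set_name), length(k)), context)
    invisible(list(k = k, off = off))
  }

  # chemotherapy sessions + molecule codes on session dates
  ct_molecule_sets <- list(
    anthracyclines = "anthracycline",
    "anthracyclines/docetaxel" = c("anthracycline", "docetaxel"),
    "anthracyclines/paclitaxel" = c("anthracycline", "paclitaxel"),
    docetaxel = "docetaxel", paclitaxel = "paclitaxel",
    other = "other_ct_molecule", unknown = character(0))
  emit_ct <- function(idx, start_off) {
    if (!length(idx)) return()
    ses <- session_block(idx, start_off, tm$ct_cycles, tm$ct_cycle_gap,
                         "ct_session")
    for (reg in names(ct_molecule_sets)) {
      sets <- ct_molecule_sets[[reg]]
      for (s in sets) {
        sel <- ct_regimen[ses$k] == reg
        if (any(sel)) {
          add_block(patient_id[ses$k[sel]],
                    index_date[ses$k[sel]] + ses$off[sel],
                    rep(pick1(s), sum(sel)), "hospital")
        }
      }
    }
  }
  emit_ct(which(ct_setting %in% c("neoadjuvant", "both")), nac_start)
  emit_ct(which(ct_setting %in% c("adjuvant", "both")), adj_ct_start)

  # radiotherapy: near-daily sessions
  session_block(which(rt), rt_start, tm$rt_sessions, 2L, "radiotherapy")

  # targeted therapy: 3-weekly courses crossing surgery when neoadjuvant
  i_tt <- which(tt)
  if (length(i_tt)) {
    k <- rep(i_tt, each = tm$tt_cycles)
    off <- tt_start[k] + tm$ct_cycle_gap *
      rep(seq_len(tm$tt_cycles) - 1L, length(i_tt))
    mol <- ifelse(tt_regimen[k] == "trastuzumab", pick1("trastuzumab"),
                  pick1("pertuzumab"))
    add_block(patient_id[k], index_date[k] + off, mol, "hospital")
    # pertuzumab is co-delivered with trastuzumab in most courses
    sel <- tt_regimen[k] == "pertuzumab+/-trastuzumab" & off == tt_start[k]
    if (any(sel)) {
      add_block(patient_id[k[sel]], index_date[k[sel]] + off[sel],
                rep(pick1("trastuzumab"), sum(sel)), "hospital")
    }
  }

  # endocrine therapy: monthly outpatient dispensings, regimen-driven
  i_et <- which(et)
  if (length(i_et)) {
    n_packs <- tm$et_duration_months
    k <- rep(i_et, each = n_packs)
    pack <- rep(seq_len(n_packs) - 1L, length(i_et))
    off <- et_start[k] + tm$et_dispense_gap * pack
    reg <- et_regimen[k]
    half <- n_packs %/% 2
    third <- n_packs %/% 3
    mol_set <- ifelse(
      reg == "tamoxifen", "tamoxifen",
      ifelse(reg == "ai", "aromatase_inhibitor",
      ifelse(reg == "tamoxifen_then_ai",
             ifelse(pack < half, "tamoxifen", "aromatase_inhibitor"),
      ifelse(reg == "ai_then_tamoxifen",
             ifelse(pack < half, "aromatase_inhibitor", "tamoxifen"),
      ifelse(reg == "tamoxifen_with_gnrh", "tamoxifen",
      ifelse(reg == "ai_with_gnrh", "aromatase_inhibitor",
             # others: tamoxifen -> AI -> tamoxifen (multi-switch)
             ifelse(pack < third, "tamoxifen",
                    ifelse(pack < 2L * third, "aromatase_inhibitor",
                           "tamoxifen"))))))))
    keep <- index_date[k] + off <= config$cutoff_date
    mol_key <- vapply(ET_MOLECULE_SET_NAMES, pick1, "")
    add_block(patient_id[k[keep]], index_date[k[keep]] + off[keep],
              unname(mol_key[mol_set[keep]]), "outpatient")
    # concomitant GnRH agonist for the "with_gnrh" regimens
    sel <- keep & reg %in% c("tamoxifen_with_gnrh", "ai_with_gnrh") &
      pack < 18L
    if (any(sel)) {
      add_block(patient_id[k[sel]], index_date[k[sel]] + off[sel],
                rep(pick1("gnrh_agonist"), sum(sel)), "outpatient")
    }
  }

  # administrative censoring can cut a dispensing plan before its molecule
  # switch; relabel the true regimen to the molecules actually delivered
  if (length(i_et)) {
    n_emitted <- pmin(
      tm$et_duration_months,
      (as.integer(config$cutoff_date - index_date) - et_start) %/%
        tm$et_dispense_gap + 1L)
    half <- tm$et_duration_months %/% 2
    third <- tm$et_duration_months %/% 3
    et_regimen <- ifelse(
      et_regimen == "tamoxifen_then_ai" & n_emitted <= half, "tamoxifen",
      ifelse(et_regimen == "ai_then_tamoxifen" & n_emitted <= half, "ai",
      ifelse(et_regimen == "others" & n_emitted <= third, "tamoxifen",
      ifelse(et_regimen == "others" & n_emitted <= 2L * third,
             "tamoxifen_then_ai", et_regimen))))
  }

  # fertility-preservation decoys: lone GnRH delivery shortly before CT
  # start in patients who never receive tamoxifen/AI
  i_decoy <- which(ct & !et & stats::runif(n) < config$fertility_decoy_prob)
  if (length(i_decoy)) {
    start <- ifelse(ct_setting[i_decoy] %in% c("neoadjuvant", "both"),
                    nac_start[i_decoy], adj_ct_start[i_decoy])
    add_block(patient_id[i_decoy], index_date[i_decoy] + start - 10L,
              rep(pick1("gnrh_agonist"), length(i_decoy)), "outpatient")
  }

  # diagnostic events
  i_b <- which(diag_mode == "biopsy")
  add_block(patient_id[i_b], first_treatment_date[i_b] + biopsy_off[i_b],
            rep(pick1("breast_biopsy"), length(i_b)), "outpatient")
  # imaging a little before the biopsy must not displace the biopsy date
  add_block(patient_id[i_b],
            first_treatment_date[i_b] + biopsy_off[i_b] - 10L,
            rep(pick1("breast_imaging"), length(i_b)), "outpatient")
  i_c <- which(diag_mode == "cytology")
  add_block(patient_id[i_c], first_treatment_date[i_c] + biopsy_off[i_c],
            rep(pick1("breast_cytology"), length(i_c)), "outpatient")
  i_i <- which(diag_mode == "imaging_only")
  if (length(i_i)) {
    anchor <- first_treatment_date[i_i] + img_anchor_off[i_i]
    add_block(patient_id[i_i], anchor,
              rep(pick1("breast_imaging"), length(i_i)), "outpatient")
    add_block(patient_id[i_i], anchor - img_gap[i_i],
              rep(pick1("breast_imaging"), length(i_i)), "outpatient")
    # an older scan beyond the one-month chaining gap: must not be reached
    add_block(patient_id[i_i], anchor - img_gap[i_i] - 45L,
              rep(pick1("breast_imaging"), length(i_i)), "outpatient")
  }

  events <- dplyr::bind_rows(blocks)
  # administrative censoring of the claims stream
  events <- events[events$event_date <= config$cutoff_date, , drop = FALSE]

  # death from per-subtype exponential hazard, pushed past the last claim
  # so included records stay chronologically consistent
  last_event <- tapply(as.integer(events$event_date), events$patient_id,
                       max)
  last_event <- as.Date(as.integer(last_event[patient_id]),
                        origin = "1970-01-01")
  death_draw <- index_date +
    as.integer(stats::rexp(n, config$annual_death_hazard[subtype] / 365.25))
  death_date <- pmax(death_draw, last_event + 1L)
  dead <- death_date <= config$cutoff_date
  death_date[!dead] <- NA

  patients <- tibble::tibble(
    patient_id = patient_id, sex = "female", birth_date = birth_date,
    insurance_plan = "general",
    vital_status = ifelse(dead, "dead", "alive"),
    death_date = death_date, inclusion_date = inclusion_date)

  # --- contaminant mutations: exactly one filter-tripping pattern each ---
  mut <- function(reason) which(exclusion_reason == reason)
  patients$sex[mut("male")] <- "male"
  i <- mut("under_18")
  patients$birth_date[i] <- patients$inclusion_date[i] - 6000L  # ~16.4 y
  patients$insurance_plan[mut("non_general_plan")] <- "other"
  i <- mut("no_surgery")
  if (length(i)) {
    surgery_codes <- unlist(dict[SURGERY_SET_NAMES], use.names = FALSE)
    drop <- events$patient_id %in% patient_id[i] &
      event_keys(events) %in% surgery_codes
    events <- events[!drop, , drop = FALSE]
  }
  extra <- list()
  i <- mut("other_cancer")
  if (length(i)) {
    extra[[length(extra) + 1]] <- tibble::tibble(
      patient_id = patient_id[i], event_date = inclusion_date[i] + 30L,
      code_system = "ICD10",
      code = sub("^ICD10:", "", code_set(dict, "other_cancer")[1]),
      care_context = "hospital")
  }
  i <- mut("prior_bc")
  if (length(i)) {
    extra[[length(extra) + 1]] <- tibble::tibble(
      patient_id = patient_id[i], event_date = inclusion_date[i] - 100L,
      code_system = "ICD10", code = "C50", care_context = "hospital")
  }
  i <- mut("metastatic")
  if (length(i)) {
    extra[[length(extra) + 1]] <- tibble::tibble(
      patient_id = patient_id[i], event_date = index_date[i] + 10L,
      code_system = "ICD10",
      code = sub("^ICD10:", "", code_set(dict, "metastasis")[1]),
      care_context = "hospital")
  }
  i <- mut("corrupt")
  if (length(i)) {
    # death recorded before later claims: chronologically impossible
    patients$vital_status[i] <- "dead"
    patients$death_date[i] <- index_date[i] + 30L
    extra[[length(extra) + 1]] <- tibble::tibble(
      patient_id = patient_id[i], event_date = index_date[i] + 300L,
      code_system = "CCAM",
      code = sub("^CCAM:", "", code_set(dict, "breast_imaging")[1]),
      care_context = "outpatient")
  }
  if (length(extra)) events <- dplyr::bind_rows(events, extra)

  bundle <- claims_bundle(patients, events)

  included <- exclusion_reason == "included"
  na_if_excluded <- function(x) {
    x[!included] <- NA
    x
  }
  ground_truth <- tibble::tibble(
    patient_id = patient_id,
    exclusion_reason = exclusion_reason,
    true_subtype = na_if_excluded(subtype),
    true_pathway = na_if_excluded(pathway),
    true_index_date = as.Date(na_if_excluded(index_date),
                              origin = "1970-01-01"),
    true_age_years = na_if_excluded(age),
    rt_received = na_if_excluded(rt), ct_received = na_if_excluded(ct),
    et_received = na_if_excluded(et), tt_received = na_if_excluded(tt),
    rt_setting = na_if_excluded(rt_setting),
    ct_setting = na_if_excluded(ct_setting),
    et_setting = na_if_excluded(et_setting),
    tt_setting = na_if_excluded(tt_setting),
    ct_regimen = na_if_excluded(ct_regimen),
    et_regimen = na_if_excluded(et_regimen),
    tt_regimen = na_if_excluded(tt_regimen),
    surgery_breast_type = na_if_excluded(
      ifelse(mastectomy, "mastectomy", "partial")),
    surgery_axillary = na_if_excluded(axillary),
    node_positive = na_if_excluded(node_positive),
    diag_mode = na_if_excluded(
      ifelse(diag_mode == "imaging_only", "imaging_only", diag_mode)),
    true_diagnosis_date = as.Date(na_if_excluded(diagnosis_date),
                                  origin = "1970-01-01"),
    true_first_treatment_date = as.Date(
      na_if_excluded(first_treatment_date), origin = "1970-01-01"),
    dead = na_if_excluded(patients$vital_status[match(
      patient_id, patients$patient_id)] == "dead"))

  structure(list(bundle = bundle, ground_truth = ground_truth,
                 config = config),
            class = "synthetic_claims")
}

#' @export
print.synthetic_claims <- function(x, ...) {
  gt <- x$ground_truth
  cat("<synthetic_claims> ", nrow(gt), " patients (",
      sum(gt$exclusion_reason == "included"), " included, ",
      sum(gt$exclusion_reason != "included"), " contaminants), ",
      nrow(x$bundle$events), " events\n", sep = "")
  invisible(x)
}
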