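test_that("a fixed seed makes the generator fully reproducible", {
  cfg <- sim_preset("contaminated", n_patients = 300, seed = 7)
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_identical(a$bundle, b$bundle)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_claims(sim_preset("contaminated", n_patients = 300,
                                  seed = 8))
  expect_false(any(c$bundle$patients$patient_id %in%
                     a$bundle$patients$patient_id))
})

test_that("a degenerate luminal no-chemo config yields surgery + ET only", {
  cfg <- sim_config(
    n_patients = 100, seed = 5,
    subtype_probs = c("luminal" = 1, "TNBC" = 0, "HER2+/HR+" = 0,
                      "HER2+/HR-" = 0, "undefined" = 0),
    pathway_probs = utils::modifyList(
      cohortpath:::default_pathway_probs(),
      list(luminal = c(surgery_no_CT = 1, surgery_then_CT = 0, NAC = 0,
                       NRT = 0, NET = 0))))
  sim <- simulate_claims(cfg)
  keys <- paste0(sim$bundle$events$code_system, ":",
                 sim$bundle$events$code)
  dict <- default_code_dictionary()
  surgery_codes <- unlist(dict[cohortpath:::SURGERY_SET_NAMES])
  et_codes <- unlist(dict[c("tamoxifen", "aromatase_inhibitor")])
  has <- function(codes) {
    unique(sim$bundle$events$patient_id[keys %in% codes])
  }
  expect_length(has(surgery_codes), 100)
  expect_length(has(et_codes), 100)
  expect_length(has(code_set(dict, "ct_session")), 0)
  expect_length(has(c(code_set(dict, "trastuzumab"),
                      code_set(dict, "pertuzumab"))), 0)
})

test_that("contaminant counts follow their binomial rates", {
  rates <- c(male = 0, under_18 = 0, non_general_plan = 0, no_surgery = 0,
             other_cancer = 0, prior_bc = 0, metastatic = 0.045,
             corrupt = 0)
  sim <- simulate_claims(sim_config(n_patients = 2000, seed = 13,
                                    contamination_rates = rates))
  n_met <- sum(sim$ground_truth$exclusion_reason == "metastatic")
  # binomial(2000, 0.045) central 99% interval
  expect_gte(n_met, qbinom(0.005, 2000, 0.045))
  expect_lte(n_met, qbinom(0.995, 2000, 0.045))
  expect_equal(sum(sim$ground_truth$exclusion_reason %in%
                     setdiff(names(rates), "metastatic")), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(subtype_probs = c(
    "luminal" = 0.5, "TNBC" = 0.2, "HER2+/HR+" = 0.2, "HER2+/HR-" = 0.2,
    "undefined" = 0.2)), class = "cohortpath_config_error")
  expect_error(sim_config(contamination_rates = c(
    male = 0.9, under_18 = 0.9, non_general_plan = 0, no_surgery = 0,
    other_cancer = 0, prior_bc = 0, metastatic = 0, corrupt = 0)),
    class = "cohortpath_config_error")
  expect_error(sim_preset("nope"), class = "cohortpath_config_error")
})

test_that("presets are valid and the realistic subtype mix is coherent", {
  for (p in c("clean_small", "realistic", "contaminated",
              "survival_demo")) {
    cfg <- sim_preset(p, n_patients = 10)
    expect_s3_class(cfg, "sim_config")
  }
  cfg <- sim_preset("realistic")
  expect_equal(sum(cfg$subtype_probs), 1, tolerance = 1e-9)
  expect_equal(unname(cfg$subtype_probs["undefined"]), 0.189)
  # defined-subtype shares: luminal/TNBC/HER2 = .802/.095/.103
  defined <- cfg$subtype_probs[c("luminal", "TNBC", "HER2+/HR+",
                                 "HER2+/HR-")]
  shares <- defined / sum(defined)
  expect_equal(unname(shares["luminal"]), 0.802, tolerance = 1e-3)
  expect_equal(unname(shares["TNBC"]), 0.095, tolerance = 1e-3)
  expect_equal(unname(shares["HER2+/HR+"] + shares["HER2+/HR-"]), 0.103,
               tolerance = 1e-3)
  expect_equal(cfg$age_mixture$mean, c(50.3, 65.0))
})

test_that("generated ground truth is internally consistent", {
  sim <- simulate_claims(sim_preset("contaminated", n_patients = 500,
                                    seed = 17))
  gt <- sim$ground_truth
  expect_equal(nrow(gt), 500)
  expect_false(any(is.na(gt$exclusion_reason)))
  inc <- gt[gt$exclusion_reason == "included", ]
  expect_false(any(is.na(inc$true_subtype)))
  expect_false(any(is.na(inc$true_pathway)))
  # treatment flags agree with the subtype inference truth table
  expect_equal(infer_subtype(inc$ct_received, inc$et_received,
                             inc$tt_received),
               inc$true_subtype)
})
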