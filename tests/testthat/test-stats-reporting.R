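mk_records <- function(n, subtype = "luminal", age = 55,
                       node = FALSE) {
  tibble::tibble(
    patient_id = sprintf("p%03d", seq_len(n)),
    age_at_diagnosis = age, age_class = as.character(age_class(age)),
    subtype = subtype, node_positive = node,
    surgery_breast_type = "partial", surgery_axillary = TRUE,
    main_pathway = "surgery_no_CT",
    survival_time_months = 24, event = FALSE)
}

mk_treatments <- function(records, ct_settings = character(0),
                          ct_regimens = NULL) {
  n <- nrow(records)
  base <- tidyr::expand_grid(patient_id = records$patient_id,
                             modality = c("surgery", "RT", "CT", "ET",
                                          "TT"))
  base$received <- base$modality == "surgery"
  base$setting <- ifelse(base$modality == "surgery", "surgery", "none")
  base$regimen <- NA_character_
  base$combination <- NA_character_
  base$start_date <- as.Date("2013-01-01")
  base$end_date <- as.Date("2013-01-01")
  base$cycles_neoadjuvant <- NA_integer_
  base$cycles_adjuvant <- NA_integer_
  for (i in seq_along(ct_settings)) {
    row <- base$modality == "CT" & base$patient_id == records$patient_id[i]
    base$received[row] <- TRUE
    base$setting[row] <- ct_settings[i]
    base$regimen[row] <- if (is.null(ct_regimens)) "unknown" else
      ct_regimens[i]
  }
  base
}

test_that("chemotherapy regimen denominator counts both-setting twice", {
  rec <- mk_records(10)
  tr <- mk_treatments(rec, ct_settings = c("both", "adjuvant", "adjuvant",
                                           "neoadjuvant"),
                      ct_regimens = c("paclitaxel", "unknown", "unknown",
                                      "docetaxel"))
  s <- summarize_cohort(rec, tr)
  reg <- s[s$variable == "CT_regimen", ]
  expect_equal(unique(reg$denominator), 5L)  # 1 + 2 + 2*1 settings
  expect_equal(reg$count[reg$class == "paclitaxel"], 2L)  # both counts 2x
  expect_equal(reg$count[reg$class == "docetaxel"], 1L)
  expect_equal(sum(reg$count), 5L)
  expect_equal(ct_setting_denominator(15627, 72939, 1686), 91938)
})

test_that("summary percents use the right denominators and sum to 100", {
  rec <- mk_records(10, subtype = c(rep("luminal", 8), "TNBC",
                                    "HER2+/HR+"))
  s <- summarize_cohort(rec, mk_treatments(rec))
  def <- s[s$variable == "subtype_defined", ]
  expect_equal(def$percent[def$class == "luminal"], 80.0)
  expect_equal(def$percent[def$class == "TNBC"], 10.0)
  expect_equal(def$percent[def$class == "HER2+/HR+"], 10.0)
  for (v in unique(s$variable)) {
    blk <- s[s$variable == v, ]
    expect_lt(abs(sum(blk$percent) - 100), 0.11)
  }
  # empty cohort: empty table, no division by zero
  s0 <- summarize_cohort(mk_records(0), mk_treatments(mk_records(0)))
  expect_equal(nrow(s0), 0)
})

test_that("small strata are suppressed below the 50-patient threshold", {
  df <- data.frame(stratum = c("a", "b", "c"), n = c(49, 50, 200))
  out <- suppress_small_strata(df)
  expect_equal(out$stratum, c("b", "c"))
  expect_equal(attr(out, "suppressed")$stratum, "a")
  expect_equal(suppress_small_strata(df[df$n >= 50, ])$stratum,
               c("b", "c"))
  expect_warning(out0 <- suppress_small_strata(data.frame(n = c(1, 2))),
                 "threshold")
  expect_equal(nrow(out0), 0)
})

test_that("KM estimator equals brute-force product-limit", {
  # independent brute-force product-limit oracle
  brute_km <- function(time, event, at) {
    s <- 1
    for (t in sort(unique(time[event == 1]))) {
      if (t > at) break
      n_risk <- sum(time >= t)
      d <- sum(time == t & event == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }
  set.seed(12)
  for (r in 1:20) {
    n <- sample(5:30, 1)
    rec <- tibble::tibble(survival_time_months = round(rexp(n, 0.02), 3),
                          event = runif(n) < 0.6,
                          age_class = "50-60", subtype = "luminal",
                          node_positive = FALSE)
    km <- km_analysis(rec)
    for (j in seq_len(nrow(km$curve))) {
      expect_equal(km$curve$estimate[j],
                   brute_km(rec$survival_time_months, rec$event,
                            km$curve$time[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("reverse KM median equals the closed form with no deaths", {
  times <- c(10, 20, 30, 40, 50)
  rec <- tibble::tibble(survival_time_months = times, event = FALSE,
                        age_class = "50-60", subtype = "luminal",
                        node_positive = FALSE)
  km <- km_analysis(rec)
  expect_equal(km$median_followup_months, median(times))
  expect_equal(km$n_events, 0)
  expect_true(all(is.na(km$logrank$p_value)))
})

test_that("log-rank on two identical groups gives chisq 0, p 1", {
  base <- tibble::tibble(survival_time_months = c(5, 10, 15, 20, 30),
                        event = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  rec <- dplyr::bind_rows(dplyr::mutate(base, grp = "a"),
                          dplyr::mutate(base, grp = "b"))
  rec$age_class <- "50-60"
  rec$subtype <- "luminal"
  rec$node_positive <- FALSE
  km <- km_analysis(rec, groupings = "grp")
  expect_equal(km$logrank$chisq, 0, tolerance = 1e-12)
  expect_equal(km$logrank$p_value, 1, tolerance = 1e-12)
  # survival curve is monotone non-increasing from 1
  expect_true(all(diff(km$curve$estimate) <= 0))
  expect_true(all(km$curve$estimate <= 1))
})

test_that("modality test handles degenerate and unimodal inputs", {
  expect_error(modality_test(rnorm(5)), class = "cohortpath_input_error")
  mt <- modality_test(rep(3.2, 50))
  expect_equal(mt$p_value, 1)
  expect_equal(mt$n_modes, 1L)
  expect_equal(mt$mode_locations, 3.2)
  set.seed(4)
  x <- rnorm(800, 60, 8)
  mt1 <- modality_test(x, reps = 200, seed = 2)
  expect_gte(mt1$p_value, 0.05)
  expect_length(mt1$mode_locations, 1)
  expect_warning(modality_test(x, reps = 50, seed = 2), "replicates")
})

test_that("modality test p-values are affine invariant and seeded", {
  set.seed(5)
  x <- c(rnorm(300, 50, 5), rnorm(300, 65, 5))
  a <- modality_test(x, reps = 150, seed = 11)
  b <- modality_test(x * 12 - 7, reps = 150, seed = 11)
  expect_equal(a$p_value, b$p_value)
  expect_equal(b$mode_locations, a$mode_locations * 12 - 7,
               tolerance = 1e-6)
  expect_equal(modality_test(x, reps = 150, seed = 11)$p_value,
               a$p_value)
})

test_that("broom-style accessors and plots work", {
  set.seed(6)
  x <- c(rnorm(200, 50, 4), rnorm(200, 66, 4))
  mt <- modality_test(x, reps = 120, seed = 3)
  expect_s3_class(tidy(mt), "tbl_df")
  expect_equal(nrow(glance(mt)), 1)
  rec <- tibble::tibble(survival_time_months = c(5, 10, 15, 20),
                        event = c(TRUE, FALSE, TRUE, FALSE),
                        age_class = "50-60", subtype = "luminal",
                        node_positive = FALSE)
  km <- km_analysis(rec)
  expect_named(glance(km), c("n", "n_events", "median_followup_months",
                             "followup_iqr_low", "followup_iqr_high"))
  expect_s3_class(autoplot(km), "ggplot")
  expect_s3_class(plot_attrition(apply_filters(clean_bundle())$attrition),
                  "ggplot")
})
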