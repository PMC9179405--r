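index <- as.Date("2013-04-01")

surg_ev <- function(offsets, set) offset_events("p1", index, offsets, set)

test_that("the index surgery is the earliest qualifying breast surgery", {
  incl <- index - 30
  ev <- dplyr::bind_rows(
    surg_ev(0, "surgery_partial_without_axillary"),
    surg_ev(40, "surgery_total_without_axillary"))
  res <- find_index_surgery(ev, incl)
  expect_equal(res$index_date, index)

  # axillary-only does not qualify as the index
  ev <- dplyr::bind_rows(surg_ev(-10, "axillary_only"),
                         surg_ev(5, "surgery_partial_without_axillary"))
  res <- find_index_surgery(ev, incl)
  expect_equal(res$index_date, index + 5)
  # but it still contributes to the axillary bin
  expect_true(bin_surgery(res$surgeries)$axillary)

  # same-day partial + total: index on that date, binned as mastectomy
  ev <- dplyr::bind_rows(surg_ev(0, "surgery_partial_without_axillary"),
                         surg_ev(0, "surgery_total_without_axillary"))
  res <- find_index_surgery(ev, incl)
  expect_equal(res$index_date, index)
  expect_equal(bin_surgery(res$surgeries)$breast_type, "mastectomy")

  expect_error(find_index_surgery(surg_ev(0, "axillary_only"), incl),
               class = "cohortpath_no_index_surgery")
})

test_that("surgery binning follows most-extensive-wins over all subsets", {
  cats <- unname(cohortpath:::SURGERY_CATEGORIES)
  # independent oracle over the category subset
  oracle <- function(subset) {
    list(breast_type = if (any(grepl("^mastectomy", subset)))
      "mastectomy" else "partial",
      axillary = any(grepl("with_axillary|axillary_only", subset)))
  }
  for (bits in 1:31) {
    subset <- cats[bitwAnd(bits, 2^(0:4)) > 0]
    got <- bin_surgery(tibble::tibble(date = index, category = subset))
    expect_equal(got, oracle(subset), info = paste(subset, collapse = "+"))
  }
})

test_that("window membership uses closed intervals on both ends", {
  w <- treatment_windows()
  det <- function(offsets, window, set, modality) {
    detect_windowed_modality(surg_ev(offsets, set), index, window,
                             code_set(DICT, set), modality)
  }
  expect_false(det(366, w$rt, "radiotherapy", "RT")$received)
  expect_true(det(365, w$rt, "radiotherapy", "RT")$received)
  expect_true(det(-150, w$rt, "radiotherapy", "RT")$received)
  expect_false(det(-151, w$rt, "radiotherapy", "RT")$received)
  ct <- det(c(-250, 180), w$ct, "ct_session", "CT")
  expect_true(ct$received)
  expect_equal(ct$setting, "both")
  expect_equal(ct$start_date, index - 250)
  expect_equal(ct$end_date, index + 180)
  expect_false(det(-300, w$tt, "trastuzumab", "TT")$received)
})

test_that("classification is invariant to shifting the whole record", {
  w <- treatment_windows()
  offsets <- c(-200, -100, 10, 170, 200)
  for (shift in c(-3000, 0, 5000)) {
    ev <- offset_events("p1", index + shift, offsets, "ct_session")
    res <- detect_windowed_modality(ev, index + shift, w$ct,
                                    code_set(DICT, "ct_session"), "CT")
    expect_true(res$received)
    expect_equal(res$setting, "both")
    expect_equal(as.numeric(res$start_date - (index + shift)), -200)
  }
})

test_that("settings partition sessions at the index date", {
  expect_equal(assign_setting(index + c(-90, -60, -30), index, "CT"),
               "neoadjuvant")
  expect_equal(assign_setting(index + c(-90, 30), index, "CT"), "both")
  # a same-day session counts as adjuvant
  expect_equal(assign_setting(index + 0, index, "CT"), "adjuvant")
  expect_equal(assign_setting(index + c(-30, 60), index, "TT"),
               "neoadjuvant_then_adjuvant")
  expect_equal(assign_setting(index + c(0, 60), index, "ET"), "adjuvant")
})

test_that("CT regimen classification matches a brute-force decision table", {
  # independent oracle over molecule flags (anthracycline, docetaxel,
  # paclitaxel, other)
  oracle <- function(a, d, p, o) {
    if (!a && !d && !p && !o) return("unknown")
    named <- list(c(TRUE, FALSE, TRUE, FALSE), # a+p
                  c(FALSE, FALSE, TRUE, FALSE), # p
                  c(TRUE, TRUE, FALSE, FALSE), # a+d
                  c(FALSE, TRUE, FALSE, FALSE), # d
                  c(TRUE, FALSE, FALSE, FALSE)) # a
    labels <- c("anthracyclines/paclitaxel", "paclitaxel",
                "anthracyclines/docetaxel", "docetaxel", "anthracyclines")
    for (i in seq_along(named)) {
      if (identical(c(a, d, p, o), named[[i]])) return(labels[i])
    }
    "other"
  }
  sets <- c("anthracycline", "docetaxel", "paclitaxel",
            "other_ct_molecule")
  sessions <- index + c(0, 21)
  for (bits in 0:15) {
    flags <- bitwAnd(bits, 2^(0:3)) > 0
    ev <- dplyr::bind_rows(
      surg_ev(c(0, 21), "ct_session"),
      lapply(sets[flags], function(s) surg_ev(0, s)))
    got <- classify_ct_regimen(ev, sessions)
    expect_equal(got, oracle(flags[1], flags[2], flags[3], flags[4]),
                 info = paste(sets[flags], collapse = "+"))
  }
  # molecule codes off the session dates do not count
  ev <- dplyr::bind_rows(surg_ev(c(0, 21), "ct_session"),
                         surg_ev(100, "paclitaxel"))
  expect_equal(classify_ct_regimen(ev, sessions), "unknown")
})

test_that("cycle counting merges near-consecutive sessions", {
  expect_equal(count_cycles(index + 21 * (0:5) + 40, index),
               list(adjuvant = 6L))
  # infusion spill-over two days later is the same cycle
  expect_equal(count_cycles(index + c(10, 12), index),
               list(adjuvant = 1L))
  # exactly at the merge gap starts a new cycle
  expect_equal(count_cycles(index + c(10, 17), index),
               list(adjuvant = 2L))
  expect_equal(count_cycles(index + c(-63, -42, -21, 10, 31, 52), index),
               list(neoadjuvant = 3L, adjuvant = 3L))
  # random timelines against an independent linear-scan oracle
  oracle <- function(days) {
    days <- sort(unique(days))
    k <- 1L
    for (i in seq_along(days)[-1]) {
      if (days[i] - days[i - 1] >= 7) k <- k + 1L
    }
    k
  }
  set.seed(42)
  for (r in 1:50) {
    days <- sort(sample(1:150, sample(1:12, 1)))
    got <- count_cycles(index + days, index)
    expect_equal(got$adjuvant, oracle(days))
  }
})

test_that("endocrine therapy detection applies the fertility rule", {
  tam <- function(offsets) offset_events("p1", index, offsets, "tamoxifen",
                                         "outpatient")
  gnrh <- function(offsets) offset_events("p1", index, offsets,
                                          "gnrh_agonist", "outpatient")
  et <- detect_endocrine_therapy(tam(60 + 30 * (0:11)), index)
  expect_true(et$received)
  expect_equal(et$setting, "adjuvant")
  expect_equal(et$end_date, index + 60 + 30 * 11 + 30)

  # lone GnRH delivery 10 days before NAC start, no tamoxifen/AI ever
  nac <- list(received = TRUE, start_date = index - 150,
              end_date = index - 45)
  expect_false(detect_endocrine_therapy(gnrh(-160), index,
                                        ct_course = nac)$received)
  # same delivery without chemotherapy context is real endocrine therapy
  expect_true(detect_endocrine_therapy(gnrh(-160), index)$received)
  # GnRH near CT start but with tamoxifen ever: retained
  ev <- dplyr::bind_rows(gnrh(-160), tam(60))
  expect_true(detect_endocrine_therapy(ev, index,
                                       ct_course = nac)$received)

  # neoadjuvant component -> neoadjuvant_then_adjuvant
  ai <- offset_events("p1", index, c(-60, -30, 0, 30),
                      "aromatase_inhibitor", "outpatient")
  expect_equal(detect_endocrine_therapy(ai, index)$setting,
               "neoadjuvant_then_adjuvant")
  # deliveries before the window do not trigger detection
  expect_false(detect_endocrine_therapy(tam(-300), index)$received)
})

test_that("ET regimen classification handles switches and combinations", {
  disp <- function(...) {
    args <- list(...)
    tibble::tibble(
      date = index + unlist(lapply(args, `[[`, "off")),
      molecule = rep(vapply(args, `[[`, "", "mol"),
                     vapply(args, function(a) length(a$off), 1L)))
  }
  seg <- function(mol, off) list(mol = mol, off = off)
  expect_equal(classify_et_regimen(disp(seg("tamoxifen", 1:3 * 30))),
               "tamoxifen")
  expect_equal(classify_et_regimen(
    disp(seg("tamoxifen", 1:24 * 30),
         seg("aromatase_inhibitor", 25:60 * 30))), "tamoxifen_then_ai")
  expect_equal(classify_et_regimen(
    disp(seg("aromatase_inhibitor", 1:24 * 30),
         seg("tamoxifen", 25:60 * 30))), "ai_then_tamoxifen")
  expect_equal(classify_et_regimen(
    disp(seg("tamoxifen", 1:12 * 30), seg("gnrh_agonist", 1:12 * 30))),
    "tamoxifen_with_gnrh")
  expect_equal(classify_et_regimen(
    disp(seg("aromatase_inhibitor", 1:12 * 30),
         seg("gnrh_agonist", 1:12 * 30))), "ai_with_gnrh")
  expect_equal(classify_et_regimen(
    disp(seg("aromatase_inhibitor", 1:12 * 30))), "ai")
  # multi-switch, GnRH alone, and three-molecule cases are "others"
  expect_equal(classify_et_regimen(
    disp(seg("tamoxifen", c(1, 3) * 30),
         seg("aromatase_inhibitor", 2 * 30))), "others")
  expect_equal(classify_et_regimen(disp(seg("gnrh_agonist", 1:3 * 30))),
               "others")
  expect_equal(classify_et_regimen(
    disp(seg("tamoxifen", 1 * 30), seg("aromatase_inhibitor", 2 * 30),
         seg("gnrh_agonist", 3 * 30))), "others")
})

test_that("ET regimen classifier is total and matches a rule oracle", {
  # independent oracle: molecule presence + single-switch predicate
  oracle <- function(d) {
    t <- d$date[d$molecule == "tamoxifen"]
    a <- d$date[d$molecule == "aromatase_inhibitor"]
    g <- d$date[d$molecule == "gnrh_agonist"]
    if (length(t) && length(a)) {
      if (length(g)) return("others")
      if (all(outer(t, a, `<`))) return("tamoxifen_then_ai")
      if (all(outer(a, t, `<`))) return("ai_then_tamoxifen")
      return("others")
    }
    if (length(t)) return(if (length(g)) "tamoxifen_with_gnrh"
                          else "tamoxifen")
    if (length(a)) return(if (length(g)) "ai_with_gnrh" else "ai")
    "others"
  }
  set.seed(99)
  mols <- c("tamoxifen", "aromatase_inhibitor", "gnrh_agonist")
  for (r in 1:200) {
    n <- sample(1:8, 1)
    d <- tibble::tibble(date = index + sort(sample(1:300, n)),
                        molecule = sample(mols, n, replace = TRUE))
    got <- classify_et_regimen(d)
    expect_true(got %in% cohortpath:::ET_REGIMENS)
    expect_equal(got, oracle(d))
  }
})

test_that("TT regimen and combination classification follow the tables", {
  tras <- function(off) offset_events("p1", index, off, "trastuzumab")
  pert <- function(off) offset_events("p1", index, off, "pertuzumab")
  sessions <- index + c(0, 21)
  expect_equal(classify_tt(tras(c(0, 21)), sessions), "trastuzumab")
  expect_equal(classify_tt(dplyr::bind_rows(tras(0), pert(21)), sessions),
               "pertuzumab+/-trastuzumab")
  expect_equal(classify_tt(pert(0), sessions), "pertuzumab+/-trastuzumab")

  course <- function(received, start = NA, end = NA, regimen = NA) {
    list(received = received, start_date = index + start,
         end_date = index + end, regimen = regimen)
  }
  tt <- course(TRUE, 10, 200)
  no_ct <- course(FALSE)
  et_yes <- course(TRUE, 60, 700)
  et_no <- course(FALSE)
  expect_equal(classify_tt_combination(tt, no_ct, et_yes), "TT-ET")
  expect_equal(classify_tt_combination(tt, no_ct, et_no), "other")
  cases <- list(
    c("anthracyclines/docetaxel", "anthracyclines/docetaxel-TT"),
    c("anthracyclines/paclitaxel", "anthracyclines/paclitaxel-TT"),
    c("docetaxel", "docetaxel-TT"),
    c("paclitaxel", "paclitaxel-TT (Tolaney)"),
    c("anthracyclines", "other"),
    c("unknown", "other"),
    c("other", "other"))
  for (cs in cases) {
    ct <- course(TRUE, 30, 150, cs[1])
    expect_equal(classify_tt_combination(tt, ct, et_no), cs[2],
                 info = cs[1])
  }
  # non-overlapping courses are never a combination
  ct_late <- course(TRUE, 300, 400, "paclitaxel")
  expect_equal(classify_tt_combination(tt, ct_late, et_no), "other")
})
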