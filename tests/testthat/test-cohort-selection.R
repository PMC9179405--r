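test_that("a clean patient passes all ten filters", {
  sel <- apply_filters(clean_bundle())
  expect_equal(sel$included, "p1")
  expect_equal(nrow(sel$attrition), 10)
  expect_equal(sel$attrition$filter_name, cohortpath:::FILTER_NAMES)
  expect_equal(sum(sel$attrition$n_excluded), 0)
})

test_that("attrition rows chain: n_after = n_before - n_excluded", {
  sim <- simulate_claims(sim_preset("contaminated", n_patients = 800,
                                    seed = 19))
  sel <- apply_filters(sim$bundle)
  a <- sel$attrition
  expect_equal(a$n_after, a$n_before - a$n_excluded)
  expect_equal(a$n_before[-1], a$n_after[-nrow(a)])
  expect_equal(a$n_after[nrow(a)], length(sel$included))
  # partition: every patient either included or excluded exactly once
  expect_equal(length(sel$included) + sum(a$n_excluded),
               nrow(sim$bundle$patients))
})

test_that("a patient failing several filters is attributed to the first", {
  # male AND metastatic: must fall at filter 3, never reach filter 9
  inclusion <- as.Date("2013-03-01")
  ev <- dplyr::bind_rows(
    ev_tbl("p1", inclusion, key1("bc_diagnosis")),
    ev_tbl("p1", inclusion + 30,
           key1("surgery_partial_without_axillary")),
    ev_tbl("p1", inclusion + 40, key1("metastasis")))
  b <- claims_bundle(pat_tbl(sex = "male"), ev)
  sel <- apply_filters(b)
  expect_length(sel$included, 0)
  expect_equal(sel$attrition$n_excluded[3], 1)
  expect_equal(sel$attrition$n_excluded[9], 0)
})

test_that("individual filters catch their target patterns", {
  inclusion <- as.Date("2013-03-01")
  base_ev <- function(id) dplyr::bind_rows(
    ev_tbl(id, inclusion, key1("bc_diagnosis")),
    ev_tbl(id, inclusion + 30,
           key1("surgery_partial_without_axillary")))
  excluded_at <- function(bundle) {
    a <- apply_filters(bundle)$attrition
    a$filter_index[a$n_excluded > 0]
  }
  # no BC code at all -> filter 1
  b <- claims_bundle(pat_tbl(), ev_tbl("p1", inclusion + 30,
                                       key1("surgery_partial_without_axillary")))
  expect_equal(excluded_at(b), 1L)
  # inclusion outside the incidence window -> filter 2
  b <- claims_bundle(pat_tbl(inclusion = "2009-05-01"),
                     dplyr::bind_rows(
                       ev_tbl("p1", "2009-05-01", key1("bc_diagnosis")),
                       ev_tbl("p1", "2009-06-01",
                              key1("surgery_partial_without_axillary"))))
  expect_equal(excluded_at(b), 2L)
  # under 18 at inclusion -> filter 4
  b <- claims_bundle(pat_tbl(birth = "1997-01-01"), base_ev("p1"))
  expect_equal(excluded_at(b), 4L)
  # surgery 400 days after inclusion -> filter 6
  b <- claims_bundle(pat_tbl(), dplyr::bind_rows(
    ev_tbl("p1", inclusion, key1("bc_diagnosis")),
    ev_tbl("p1", inclusion + 400,
           key1("surgery_partial_without_axillary"))))
  expect_equal(excluded_at(b), 6L)
  # prior BC code in the look-back year -> filter 8
  b <- claims_bundle(pat_tbl(), dplyr::bind_rows(
    base_ev("p1"), ev_tbl("p1", inclusion - 100, key1("bc_diagnosis"))))
  expect_equal(excluded_at(b), 8L)
  # metastasis outside its window is NOT an exclusion
  b <- claims_bundle(pat_tbl(), dplyr::bind_rows(
    base_ev("p1"), ev_tbl("p1", inclusion - 400, key1("metastasis"))))
  expect_length(excluded_at(b), 0)
  # claim after recorded death -> filter 10
  b <- claims_bundle(pat_tbl(vital = "dead", death = "2013-06-01"),
                     dplyr::bind_rows(
                       base_ev("p1"),
                       ev_tbl("p1", "2013-08-01", key1("breast_imaging"))))
  expect_equal(excluded_at(b), 10L)
})

test_that("the included set is invariant to event row order", {
  sim <- simulate_claims(sim_preset("contaminated", n_patients = 400,
                                    seed = 23))
  ev <- sim$bundle$events
  set.seed(1)
  shuffled <- claims_bundle(sim$bundle$patients,
                            ev[sample.int(nrow(ev)), ])
  expect_setequal(apply_filters(shuffled)$included,
                  apply_filters(sim$bundle)$included)
})

test_that("an empty bundle yields a zero-count report, not an error", {
  b <- claims_bundle(pat_tbl()[0, ],
                     ev_tbl("p1", "2013-01-01", "ICD10:C50")[0, ])
  sel <- apply_filters(b)
  expect_length(sel$included, 0)
  expect_equal(sum(sel$attrition$n_before), 0)
  expect_equal(sum(sel$attrition$n_excluded), 0)
})
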