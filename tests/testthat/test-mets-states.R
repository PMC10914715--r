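base_record <- function(...) {
  rec <- tibble::tibble(
    sex = "male", waist_cm = 80, sbp_mmhg = 120, dbp_mmhg = 75,
    fbg_mmol_l = 5.0, tg_mmol_l = 1.2, hdl_mmol_l = 1.4,
    treated_htn = FALSE, treated_glu = FALSE, treated_hdl = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) rec[[nm]] <- mods[[nm]]
  rec
}

test_that("component cutoffs are inclusive/exclusive exactly as defined", {
  # waist: >= 85 male / >= 80 female
  expect_true(classify_components(base_record(waist_cm = 85))$central_obesity)
  expect_false(classify_components(base_record(waist_cm = 84.99))$central_obesity)
  expect_true(classify_components(base_record(sex = "female", waist_cm = 80))$central_obesity)
  # HDL: strict < (sex-specific)
  expect_false(classify_components(base_record(sex = "female", hdl_mmol_l = 1.29))$low_hdl)
  expect_true(classify_components(base_record(sex = "female", hdl_mmol_l = 1.2899))$low_hdl)
  expect_true(classify_components(base_record(hdl_mmol_l = 1.02))$low_hdl)
  # blood pressure: either limb or treatment
  expect_true(classify_components(base_record(sbp_mmhg = 130))$hypertension)
  expect_true(classify_components(base_record(dbp_mmhg = 85))$hypertension)
  expect_true(classify_components(base_record(treated_htn = TRUE))$hypertension)
  expect_false(classify_components(base_record())$hypertension)
  # glucose and triglycerides
  expect_true(classify_components(base_record(fbg_mmol_l = 5.6))$high_fbg)
  expect_true(classify_components(base_record(treated_glu = TRUE))$high_fbg)
  expect_true(classify_components(base_record(tg_mmol_l = 1.7))$high_tg)
})

test_that("missing measurements error unless a treatment flag decides the criterion", {
  expect_error(classify_components(base_record(fbg_mmol_l = NA)),
               "high_fbg")
  # treated: the flag decides, no error
  ok <- classify_components(base_record(fbg_mmol_l = NA, treated_glu = TRUE))
  expect_true(ok$high_fbg)
  kept <- classify_components(base_record(tg_mmol_l = NA), na_action = "keep")
  expect_true(is.na(kept$high_tg))
  expect_error(classify_components(dplyr::mutate(base_record(), sex = NULL)),
               "sex")
})

test_that("state staging maps component counts and is order-invariant", {
  expect_equal(as.character(classify_state(c(0, 1, 2, 3, 4, 5))),
               c("FMD", "MMD", "SMD", "MetS", "MetS", "MetS"))
  # any three abnormal components give MetS regardless of which three
  combos <- utils::combn(5, 3)
  fields <- list(
    function(r) dplyr::mutate(r, waist_cm = 90),
    function(r) dplyr::mutate(r, sbp_mmhg = 140),
    function(r) dplyr::mutate(r, fbg_mmol_l = 6.0),
    function(r) dplyr::mutate(r, tg_mmol_l = 2.0),
    function(r) dplyr::mutate(r, hdl_mmol_l = 0.9)
  )
  for (j in seq_len(ncol(combos))) {
    rec <- base_record()
    for (k in combos[, j]) rec <- fields[[k]](rec)
    expect_equal(as.character(classify_components(rec)$state), "MetS")
  }
})

test_that("transition labels follow the state ordering and are antisymmetric", {
  expect_equal(as.character(label_transition("MMD", "SMD")), "forward")
  expect_equal(as.character(label_transition("MetS", "FMD")), "reverse")
  expect_equal(as.character(label_transition("SMD", "SMD")), "unchanged")
  states <- mets_states
  for (a in states) for (b in states) {
    ab <- as.character(label_transition(a, b))
    ba <- as.character(label_transition(b, a))
    if (ab == "forward") expect_equal(ba, "reverse")
    if (ab == "unchanged") expect_equal(ba, "unchanged")
  }
  expect_error(label_transition("MMD", "bogus"), "unknown state")
})

test_that("cohort accounting reproduces printed percentages from their counts", {
  staged <- printed_counts_cohort()
  s <- cohort_summary(staged)
  expect_equal(s$n, 5581)
  expect_equal(s$baseline_mets, 2479)
  expect_equal(s$followup_mets, 2572)
  expect_equal(s$new_mets, 863)
  expect_equal(round(s$cumulative_incidence_pct, 2), 27.82)
  expect_equal(s$unchanged_n, 2719)
  expect_equal(round(s$unchanged_pct, 2), 48.72)
  expect_equal(s$forward_n, 1543)
  expect_equal(round(s$forward_pct_of_changes, 2), 53.91)
  expect_equal(s$reverse_n, 1319)
  expect_equal(round(s$reverse_pct_of_changes, 2), 46.09)
})

test_that("an all-unchanged cohort reports undefined change shares", {
  staged <- tibble::tibble(state_bl = c("FMD", "MetS"), state_fu = c("FMD", "MetS"))
  s <- cohort_summary(staged)
  expect_equal(s$changes_n, 0)
  expect_true(is.na(s$forward_pct_of_changes))
  expect_true(is.na(s$reverse_pct_of_changes))
  expect_equal(s$cumulative_incidence_pct, 0)
})

test_that("two-wave staging classifies both waves and drops incomplete subjects", {
  coh <- tibble::tibble(
    sex = c("male", "female"),
    waist_cm_bl = c(90, 70), sbp_mmhg_bl = c(140, 110), dbp_mmhg_bl = c(90, 70),
    fbg_mmol_l_bl = c(6.0, 5.0), tg_mmol_l_bl = c(2.0, 1.0),
    hdl_mmol_l_bl = c(0.9, 1.5),
    waist_cm_fu = c(80, 70), sbp_mmhg_fu = c(120, 110), dbp_mmhg_fu = c(70, 70),
    fbg_mmol_l_fu = c(5.0, NA), tg_mmol_l_fu = c(1.0, 1.0),
    hdl_mmol_l_fu = c(1.2, 1.5)
  )
  expect_message(st <- add_mets_staging(coh), "excluded")
  expect_equal(nrow(st), 1)
  expect_equal(as.character(st$state_bl), "MetS")
  expect_equal(as.character(st$state_fu), "FMD")
  expect_equal(as.character(st$transition), "reverse")
})
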