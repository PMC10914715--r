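test_that("forward sampling is reproducible and honors degenerate CPTs", {
  det <- bnet(
    variables = list(a = c("no", "yes"), b = c("0", "1")),
    cpts = list(
      a = list(parents = character(), prob = c(0, 1)),
      b = list(parents = "a", prob = rbind(c(1, 0), c(0, 1)))
    )
  )
  d <- sample_from_network(det, 200, seed = 4)
  expect_true(all(d$a == "yes"))
  expect_true(all(d$b == "1"))

  empty <- sample_from_network(det, 0, seed = 4)
  expect_equal(nrow(empty), 0)
  expect_equal(colnames(empty), c("a", "b"))

  net <- build_published_fixture("progression")
  expect_identical(sample_from_network(net, 500, seed = 8),
                   sample_from_network(net, 500, seed = 8))
})

test_that("empirical frequencies match the exact marginal within Monte-Carlo error", {
  net <- build_published_fixture("progression")
  n <- 100000
  d <- sample_from_network(net, n, seed = 13)
  p_exact <- bn_query(net, "progression")$probability[2]
  p_hat <- mean(d$progression == "forward")
  se <- sqrt(p_exact * (1 - p_exact) / n)
  expect_lt(abs(p_hat - p_exact), 3 * se)
})

test_that("published fixtures validate and reproduce the printed quantities", {
  for (which in c("progression", "recovery")) {
    net <- build_published_fixture(which)
    expect_equal(nrow(validate_bnet(net)), 0)
  }
  prog <- build_published_fixture("progression")
  expect_equal(bn_query(prog, "hyperuricemia")$probability, c(0.9159, 0.0841),
               tolerance = 1e-6)
  expect_equal(bn_query(prog, "bmi")$probability, c(0.4791, 0.0572, 0.4637),
               tolerance = 1e-6)
  td <- tidy(prog)
  expect_equal(
    td$probability[td$node == "progression" &
                     td$parent_config == "hyperuricemia=yes, bmi=overweight" &
                     td$level == "forward"],
    0.7199
  )
  rec <- build_published_fixture("recovery")
  expect_equal(bn_query(rec, "hba1c")$probability, c(0.9272, 0.0728),
               tolerance = 1e-6)
  expect_equal(bn_query(rec, "bmi")$probability, c(0.5384, 0.0701, 0.3915),
               tolerance = 1e-6)
  tr <- tidy(rec)
  expect_equal(
    tr$probability[tr$node == "recovery" &
                     tr$parent_config == "hba1c=no, bmi=thin" &
                     tr$level == "reverse"],
    0.4565
  )
  # the printed over-unit row is renormalized
  renorm <- tr$probability[tr$node == "recovery" &
                             tr$parent_config == "hba1c=yes, bmi=normal"]
  expect_equal(sum(renorm), 1, tolerance = 1e-12)
  expect_equal(renorm[2], 0.2497 / 1.0030, tolerance = 1e-12)
})

test_that("generated cohorts realize the drawn transitions after reclassification", {
  coh <- generate_cohort(4000, seed = 21)
  st <- add_mets_staging(coh)
  expect_equal(nrow(st), 4000) # no subject lost to missing criteria
  agree <- mean(as.character(st$transition) == as.character(st$sim_transition))
  expect_gte(agree, 0.99)
  expect_true(all(st$state_bl != "MetS")) # progression at-risk population

  rec <- generate_cohort(4000, seed = 22, outcome = "recovery")
  str <- add_mets_staging(rec)
  agree_r <- mean(as.character(str$transition) == as.character(str$sim_transition))
  expect_gte(agree_r, 0.99)
  expect_true(all(str$state_bl != "FMD")) # recovery at-risk population
})

test_that("a transition CPT forced to stay put yields an all-unchanged cohort", {
  stay <- matrix(0, 2, 3, dimnames = list(c("no", "yes"),
                                          c("normal", "thin", "overweight")))
  coh <- generate_cohort(1500, seed = 5,
                         config = cohort_config(progression_cpt = stay))
  st <- add_mets_staging(coh)
  expect_true(all(st$transition == "unchanged"))
})

test_that("cohorts are bit-reproducible and component prevalences plausible", {
  a <- generate_cohort(1000, seed = 99)
  b <- generate_cohort(1000, seed = 99)
  expect_identical(a, b)
  st <- add_mets_staging(a)
  prev <- colMeans(st[, c("central_obesity_bl", "hypertension_bl", "high_fbg_bl",
                          "high_tg_bl", "low_hdl_bl")])
  expect_true(all(prev > 0.10 & prev < 0.50))
})

test_that("the transition frequencies track the configured CPT", {
  coh <- generate_cohort(20000, seed = 7)
  st <- add_mets_staging(coh)
  sub <- st[st$hyperuricemia == "yes" & st$bmi_level == "overweight", ]
  expect_equal(mean(sub$transition == "forward"), 0.7199, tolerance = 0.02)
})

test_that("structure learning on a generated cohort recovers the outcome's parents", {
  coh <- generate_cohort(10000, seed = 17)
  st <- add_mets_staging(coh)
  model_data <- data.frame(
    gender = st$sex, age = st$age_group, exercise = st$exercise,
    hyperuricemia = st$hyperuricemia, bmi = st$bmi_level,
    progression = droplevels(st$transition)
  )
  hc <- hill_climb(model_data)
  expect_true(any(hc$from == "hyperuricemia" & hc$to == "progression"))
  expect_true(any(hc$from == "bmi" & hc$to == "progression"))
})
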