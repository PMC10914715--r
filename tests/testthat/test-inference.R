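test_that("variable elimination equals enumeration on fixtures and random nets", {
  for (which in c("progression", "recovery")) {
    net <- build_published_fixture(which)
    outcome <- if (which == "progression") "progression" else "recovery"
    cases <- list(
      list(target = outcome, evidence = list()),
      list(target = outcome, evidence = list(bmi = "overweight")),
      list(target = "bmi", evidence = setNames(list(net$variables[[outcome]][2]), outcome))
    )
    for (cs in cases) {
      q <- bn_query(net, cs$target, cs$evidence)
      e <- enumerate_posterior(net, cs$target, cs$evidence)
      expect_equal(q$probability, e$probability, tolerance = 1e-12)
      expect_equal(sum(q$probability), 1, tolerance = 1e-12)
    }
  }
  for (seed in 1:200) {
    net <- random_net(seed)
    cs <- random_query_case(net, seed + 9000)
    q <- bn_query(net, cs$target, cs$evidence)
    e <- enumerate_posterior(net, cs$target, cs$evidence)
    expect_equal(q$probability, e$probability, tolerance = 1e-12)
  }
})

test_that("evidence on a chain inverts by Bayes' rule (hand enumeration)", {
  # a -> b -> c, all binary
  pa <- c(0.3, 0.7)
  pb <- rbind(c(0.8, 0.2), c(0.4, 0.6)) # rows: a level
  pc <- rbind(c(0.9, 0.1), c(0.25, 0.75)) # rows: b level
  net <- bnet(
    variables = list(a = c("0", "1"), b = c("0", "1"), c = c("0", "1")),
    cpts = list(
      a = list(parents = character(), prob = pa),
      b = list(parents = "a", prob = pb),
      c = list(parents = "b", prob = pc)
    )
  )
  # P(a | c = 1) by explicit 8-term summation
  joint <- function(i, j, k) pa[i] * pb[i, j] * pc[j, k]
  num <- c(
    joint(1, 1, 2) + joint(1, 2, 2),
    joint(2, 1, 2) + joint(2, 2, 2)
  )
  expected <- num / sum(num)
  got <- bn_query(net, "a", c(c = "1"))
  expect_equal(got$probability, expected, tolerance = 1e-14)
})

test_that("fixing all parents returns the CPT row itself", {
  net <- restricted_progression_net()
  q <- bn_query(net, "progression",
                c(hyperuricemia = "yes", bmi = "overweight"))
  expect_equal(q$probability, c(0.2801, 0.7199), tolerance = 1e-12)
})

test_that("zero-probability evidence raises a dedicated error", {
  net <- bnet(
    variables = list(a = c("no", "yes"), b = c("no", "yes")),
    cpts = list(
      a = list(parents = character(), prob = c(1, 0)),
      b = list(parents = "a", prob = rbind(c(0.5, 0.5), c(0.5, 0.5)))
    )
  )
  expect_error(bn_query(net, "b", c(a = "yes")), class = "metsbn_zero_evidence")
  expect_error(enumerate_posterior(net, "b", c(a = "yes")),
               class = "metsbn_zero_evidence")
  # outcome level with zero prior mass, conditioned on as evidence
  net2 <- bnet(
    variables = list(a = c("no", "yes"), b = c("no", "yes")),
    cpts = list(
      a = list(parents = character(), prob = c(0.4, 0.6)),
      b = list(parents = "a", prob = rbind(c(1, 0), c(1, 0)))
    )
  )
  expect_error(evidential_reasoning(net2, "b", "yes", "a"),
               class = "metsbn_zero_evidence")
})

test_that("evidence moves the outcome monotonically in the risk factor", {
  net <- build_published_fixture("progression")
  base <- bn_query(net, "progression")$probability[2]
  up <- bn_query(net, "progression", c(hyperuricemia = "yes"))$probability[2]
  dn <- bn_query(net, "progression", c(hyperuricemia = "no"))$probability[2]
  expect_gt(up, base)
  expect_gt(base, dn)
})

test_that("reasoning tables normalize and satisfy the Bayes-inversion identity", {
  net <- build_published_fixture("progression")
  factors <- c("hyperuricemia", "bmi", "gender")
  ca <- causal_reasoning(net, "progression", factors)
  sums <- ca |>
    dplyr::summarise(s = sum(.data$posterior),
                     .by = c("variable", "evidence_level"))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)

  ev <- evidential_reasoning(net, "progression", "forward", factors)
  sums2 <- ev |> dplyr::summarise(s = sum(.data$posterior), .by = "variable")
  expect_equal(sums2$s, rep(1, nrow(sums2)), tolerance = 1e-9)

  # P(f | o) = P(o | f) P(f) / P(o), term by term
  p_o <- bn_query(net, "progression")$probability[2]
  for (i in seq_len(nrow(ev))) {
    p_f <- ev$prior[i]
    p_o_f <- ca$posterior[ca$variable == ev$variable[i] &
                            ca$evidence_level == ev$level[i] &
                            ca$outcome_level == "forward"]
    expect_equal(ev$posterior[i], p_o_f * p_f / p_o, tolerance = 1e-12)
  }
  expect_true(all(ev$direction %in% c("↑", "↓", "=")))
})

test_that("a factor with no path to the outcome has zero delta", {
  net <- bnet(
    variables = list(a = c("0", "1"), y = c("0", "1"), iso = c("0", "1")),
    cpts = list(
      a = list(parents = character(), prob = c(0.3, 0.7)),
      y = list(parents = "a", prob = rbind(c(0.9, 0.1), c(0.2, 0.8))),
      iso = list(parents = character(), prob = c(0.6, 0.4))
    )
  )
  ca <- causal_reasoning(net, "y", c("a", "iso"))
  expect_true(all(abs(ca$delta[ca$variable == "iso"]) < 1e-12))
  expect_true(any(abs(ca$delta[ca$variable == "a"]) > 0.1))
})
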