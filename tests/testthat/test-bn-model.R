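test_that("validation accepts a sound net and names each violation", {
  ok <- bnet(
    variables = list(a = c("no", "yes")),
    cpts = list(a = list(parents = character(), prob = c(0.5, 0.5)))
  )
  expect_equal(nrow(validate_bnet(ok)), 0)

  bad_row <- bnet(
    variables = list(a = c("no", "yes")),
    cpts = list(a = list(parents = character(), prob = c(0.7, 0.4))),
    check = FALSE
  )
  v <- validate_bnet(bad_row)
  expect_equal(nrow(v), 1)
  expect_match(v$violation, "row 1 of node 'a'")

  cyclic <- bnet(
    variables = list(a = c("no", "yes"), b = c("no", "yes")),
    cpts = list(
      a = list(parents = "b", prob = rbind(c(0.5, 0.5), c(0.5, 0.5))),
      b = list(parents = "a", prob = rbind(c(0.5, 0.5), c(0.5, 0.5)))
    ),
    check = FALSE
  )
  expect_match(validate_bnet(cyclic)$violation, "cycle", all = FALSE)
})

test_that("joint probability factorizes over the CPTs", {
  one <- bnet(
    variables = list(a = c("no", "yes")),
    cpts = list(a = list(parents = character(), prob = c(0.5, 0.5)))
  )
  expect_equal(joint_probability(one, c(a = "yes")), 0.5)

  net <- restricted_progression_net()
  # product of the two root priors and the outcome CPT entry
  expect_equal(
    joint_probability(net, c(hyperuricemia = "yes", bmi = "overweight",
                             progression = "forward")),
    0.0841 * 0.4637 * 0.7199,
    tolerance = 1e-12
  )
  expect_error(
    joint_probability(net, c(hyperuricemia = "yes", bmi = "overweight")),
    "progression"
  )
  expect_error(
    joint_probability(net, c(hyperuricemia = "maybe", bmi = "overweight",
                             progression = "forward")),
    "maybe"
  )
})

test_that("the joint distribution over all full assignments sums to one", {
  for (seed in 1:20) {
    net <- random_net(seed, min_nodes = 3, max_nodes = 6)
    grid <- expand.grid(net$variables, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    total <- sum(vapply(seq_len(nrow(grid)), function(i) {
      joint_probability(net, unlist(grid[i, ]))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("count_dags matches exhaustive enumeration and big-integer values", {
  for (n in 0:4) expect_identical(as.numeric(count_dags(n)), as.numeric(brute_count_dags(n)))
  # beyond double precision the count is returned as an exact decimal string
  expect_identical(count_dags(10), "4175098976430598143")
  expect_error(count_dags(-1), "non-negative")
  expect_error(count_dags(2.5), "integer")
})

test_that("CPT row policy renormalizes small deviations and rejects large ones", {
  # printed tables rounded to 2 dp can be off by a few 1e-4: rejected
  expect_error(
    bnet(
      variables = list(a = c("no", "yes")),
      cpts = list(a = list(parents = character(), prob = c(0.5, 0.5005)))
    ),
    "sums to"
  )
  nudged <- bnet(
    variables = list(a = c("no", "yes")),
    cpts = list(a = list(parents = character(), prob = c(0.5, 0.5 + 5e-7)))
  )
  expect_equal(sum(nudged$cpts$a$prob), 1, tolerance = 1e-12)
})

test_that("JSON round trip reproduces the joint bit-for-bit; BIF export is well formed", {
  net <- build_published_fixture("progression")
  path <- withr::local_tempfile(fileext = ".json")
  write_bnet_json(net, path)
  back <- read_bnet_json(path)
  set.seed(1)
  for (i in 1:25) {
    a <- vapply(names(net$variables), function(v) sample(net$variables[[v]], 1),
                character(1))
    expect_identical(joint_probability(net, a), joint_probability(back, a))
  }
  expect_identical(names(back$variables), names(net$variables))

  bif <- withr::local_tempfile(fileext = ".bif")
  write_bnet_bif(net, bif)
  txt <- readLines(bif)
  expect_true(any(grepl("^network", txt)))
  expect_true(any(grepl("probability \\( progression \\| hyperuricemia, bmi \\)", txt)))
  expect_equal(sum(grepl("^variable ", txt)), length(net$variables))
})

test_that("tidy and glance expose the CPTs and model size", {
  net <- restricted_progression_net()
  td <- tidy(net)
  expect_true(all(c("node", "parent_config", "level", "probability") %in% names(td)))
  row <- td[td$node == "progression" &
              td$parent_config == "hyperuricemia=yes, bmi=overweight" &
              td$level == "forward", ]
  expect_equal(row$probability, 0.7199)
  gl <- glance(net)
  expect_equal(gl$nodes, 3)
  expect_equal(gl$arcs, 2)
  expect_equal(gl$parameters, 1 + 2 + 6)
})
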