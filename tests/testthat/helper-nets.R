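# Random small networks with strictly positive CPTs (Dirichlet rows), used
# by the inference and model property tests.
random_net <- function(seed, min_nodes = 3, max_nodes = 8) {
  set.seed(seed)
  n <- sample(min_nodes:max_nodes, 1)
  nodes <- sprintf("v%02d", seq_len(n))
  nlev <- sample(2:3, n, replace = TRUE)
  variables <- setNames(lapply(seq_len(n), function(i) {
    paste0("l", seq_len(nlev[i]))
  }), nodes)
  ord <- sample(nodes)
  cpts <- list()
  for (j in seq_along(ord)) {
    v <- ord[j]
    pool <- ord[seq_len(j - 1)]
    parents <- pool[runif(length(pool)) < 0.4]
    if (length(parents) > 3) parents <- sample(parents, 3)
    r <- length(variables[[v]])
    q <- prod(vapply(parents, function(p) length(variables[[p]]), integer(1)))
    rows <- t(vapply(seq_len(q), function(t) {
      g <- stats::rgamma(r, 1) + 0.05
      g / sum(g)
    }, numeric(r)))
    cpts[[v]] <- if (length(parents) == 0) {
      list(parents = character(), prob = as.numeric(rows[1, ]))
    } else {
      list(parents = parents, prob = rows)
    }
  }
  bnet(variables, cpts[nodes])
}

# random evidence set (possibly empty) and a target outside it
random_query_case <- function(net, seed) {
  set.seed(seed)
  nodes <- names(net$variables)
  k <- sample(0:min(2, length(nodes) - 1), 1)
  ev_vars <- if (k > 0) sample(nodes, k) else character()
  evidence <- setNames(lapply(ev_vars, function(v) {
    sample(net$variables[[v]], 1)
  }), ev_vars)
  target <- sample(setdiff(nodes, ev_vars), 1)
  list(target = target, evidence = evidence)
}

# exhaustive count of labeled DAGs by filtering all digraphs (n <= 4)
brute_count_dags <- function(n) {
  if (n == 0) return(1)
  pairs <- which(diag(n) == 0, arr.ind = TRUE)
  m <- nrow(pairs)
  is_acyclic <- function(A) {
    left <- seq_len(n)
    repeat {
      if (length(left) == 0) return(TRUE)
      indeg <- colSums(A[left, left, drop = FALSE])
      src <- left[indeg == 0]
      if (length(src) == 0) return(FALSE)
      left <- setdiff(left, src)
    }
  }
  count <- 0
  for (code in 0:(2^m - 1)) {
    A <- matrix(0L, n, n)
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A[pairs] <- bits
    if (is_acyclic(A)) count <- count + 1
  }
  count
}

# all DAG edge sets on the given nodes (used for the 3-node exhaustive
# scoring oracle)
all_dags <- function(nodes) {
  n <- length(nodes)
  pairs <- which(diag(n) == 0, arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (code in 0:(2^m - 1)) {
    A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    A[pairs] <- as.integer(intToBits(code))[seq_len(m)]
    parents <- lapply(nodes, function(v) nodes[A[, v] == 1])
    names(parents) <- nodes
    ok <- !is.null(metsbn:::topo_order(parents))
    if (ok) {
      idx <- which(A == 1, arr.ind = TRUE)
      out[[length(out) + 1]] <- data.frame(from = nodes[idx[, 1]],
                                           to = nodes[idx[, 2]])
    }
  }
  out
}

# staged cohort realizing the published transition counts: state pairs
# solved from the printed marginal counts of the source survey
printed_counts_cohort <- function() {
  pairs <- rbind(
    c("MetS", "MetS", 1709),
    c("MetS", "SMD", 770),
    c("SMD", "MMD", 549),
    c("FMD", "MMD", 680),
    c("SMD", "MetS", 863),
    c("FMD", "FMD", 1010)
  )
  tibble::tibble(
    state_bl = rep(pairs[, 1], as.integer(pairs[, 3])),
    state_fu = rep(pairs[, 2], as.integer(pairs[, 3]))
  )
}

# the three-node restriction of the progression network (both risk factors
# as roots with their marginal priors)
restricted_progression_net <- function() {
  bnet(
    variables = list(
      hyperuricemia = c("no", "yes"),
      bmi = c("normal", "thin", "overweight"),
      progression = c("unchanged", "forward")
    ),
    cpts = list(
      hyperuricemia = list(parents = character(), prob = c(0.9159, 0.0841)),
      bmi = list(parents = character(), prob = c(0.4791, 0.0572, 0.4637)),
      progression = list(
        parents = c("hyperuricemia", "bmi"),
        prob = rbind(
          c(0.7061, 0.2939), c(0.6573, 0.3427), c(0.6200, 0.3800),
          c(0.4500, 0.5500), c(0.9468, 0.0532), c(0.2801, 0.7199)
        )
      )
    )
  )
}
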