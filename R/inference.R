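# ---- discrete factor algebra (arrays with a vars vector) -------------------

new_factor <- function(vars, val) list(vars = vars, val = val)

cpt_factor <- function(net, v) {
  cp <- net$cpts[[v]]
  new_factor(c(v, cp$parents), cp$prob)
}

f_sizes <- function(f) {
  d <- dim(f$val)
  if (is.null(d)) length(f$val) else d
}

# restrict a factor to var = level (drops the variable)
f_reduce <- function(f, var, li) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  sizes <- f_sizes(f)
  perm <- c(pos, setdiff(seq_along(f$vars), pos))
  arr <- aperm(array(f$val, dim = sizes), perm)
  m <- matrix(arr, nrow = sizes[pos])
  rest <- sizes[perm[-1]]
  val <- array(m[li, ], dim = if (length(rest)) rest else 1)
  new_factor(f$vars[perm[-1]], if (length(rest)) val else as.numeric(val))
}

# expand a factor to a variable union, in the order of `uvars`
f_expand <- function(f, uvars, usizes) {
  if (length(f$vars) == 0) {
    return(new_factor(uvars, array(as.numeric(f$val), dim = usizes)))
  }
  missing <- setdiff(uvars, f$vars)
  sizes <- f_sizes(f)
  arr <- array(f$val, dim = c(sizes, usizes[match(missing, uvars)]))
  cur <- c(f$vars, missing)
  new_factor(uvars, aperm(arr, match(uvars, cur)))
}

f_product <- function(f1, f2, net_sizes) {
  if (length(f1$vars) == 0 && length(f2$vars) == 0) {
    return(new_factor(character(), as.numeric(f1$val) * as.numeric(f2$val)))
  }
  uvars <- union(f1$vars, f2$vars)
  usizes <- net_sizes[uvars]
  a <- f_expand(f1, uvars, usizes)
  b <- f_expand(f2, uvars, usizes)
  new_factor(uvars, array(as.numeric(a$val) * as.numeric(b$val), dim = usizes))
}

f_sum_out <- function(f, var) {
  pos <- match(var, f$vars)
  sizes <- f_sizes(f)
  perm <- c(setdiff(seq_along(f$vars), pos), pos)
  arr <- aperm(array(f$val, dim = sizes), perm)
  rest <- sizes[perm[-length(perm)]]
  m <- matrix(arr, ncol = sizes[pos])
  val <- rowSums(m)
  if (length(rest) == 0) return(new_factor(character(), sum(val)))
  new_factor(f$vars[perm[-length(perm)]], array(val, dim = rest))
}

check_evidence <- function(net, evidence) {
  evidence <- as.list(evidence)
  for (v in names(evidence)) {
    if (!v %in% bn_nodes(net)) abort(paste0("unknown evidence variable '", v, "'"))
    if (!evidence[[v]] %in% bn_levels(net, v)) {
      abort(paste0("'", evidence[[v]], "' is not a level of variable '", v, "'"))
    }
  }
  evidence
}

# exact P(target | evidence) by variable elimination; named numeric vector
ve_query <- function(net, target, evidence = list()) {
  evidence <- check_evidence(net, evidence)
  if (target %in% names(evidence)) {
    abort("`target` must not appear in `evidence`")
  }
  if (!target %in% bn_nodes(net)) abort(paste0("unknown target '", target, "'"))
  sizes <- vapply(net$variables, length, integer(1))
  factors <- lapply(bn_nodes(net), function(v) cpt_factor(net, v))
  for (v in names(evidence)) {
    li <- match(evidence[[v]], bn_levels(net, v))
    factors <- lapply(factors, f_reduce, var = v, li = li)
  }
  elim <- setdiff(bn_nodes(net), c(target, names(evidence)))
  while (length(elim) > 0) {
    # min-degree on the graph where variables co-occurring in a factor are
    # adjacent; ties lexicographic (order affects speed only)
    deg <- vapply(elim, function(v) {
      nb <- unique(unlist(lapply(factors, function(f) {
        if (v %in% f$vars) f$vars else character()
      })))
      length(setdiff(nb, v))
    }, integer(1))
    v <- sort(elim[deg == min(deg)])[1]
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prodf <- Reduce(function(x, y) f_product(x, y, sizes), factors[touch])
    factors <- c(factors[!touch], list(f_sum_out(prodf, v)))
    elim <- setdiff(elim, v)
  }
  res <- Reduce(function(x, y) f_product(x, y, sizes), factors)
  if (!identical(res$vars, target)) res <- f_expand(res, target, sizes[target])
  p <- as.numeric(res$val)
  tot <- sum(p)
  if (tot <= 0) {
    abort("zero-probability evidence: the observed evidence set has probability 0 under the network",
          class = "metsbn_zero_evidence")
  }
  setNames(p / tot, bn_levels(net, target))
}

#' Exact posterior query on a Bayesian network
#'
#' Computes \eqn{P(\text{target} \mid \text{evidence})} exactly by
#' variable elimination (min-degree elimination order over the factors'
#' co-occurrence graph; the order affects speed only, never the values).
#' Evidence is hard: each observed variable is instantiated at 100%.
#'
#' @param net A valid `bnet`.
#' @param target A variable name, not among the evidence.
#' @param evidence Named character vector or list of observed levels
#'   (possibly empty).
#' @return A tibble with columns `level` and `probability` (summing to 1).
#' @examples
#' net <- build_published_fixture("progression")
#' bn_query(net, "progression", c(hyperuricemia = "yes"))
#' @export
bn_query <- function(net, target, evidence = list()) {
  p <- ve_query(net, target, evidence)
  tibble(level = names(p), probability = unname(p))
}

#' Brute-force posterior by full-joint enumeration
#'
#' Reference implementation against which [bn_query()] is property-tested:
#' enumerates every full assignment, multiplies the CPT entries, and
#' conditions on the evidence. Exponential in the number of nodes; capped
#' at 15.
#'
#' @inheritParams bn_query
#' @return A tibble with columns `level` and `probability`.
#' @export
enumerate_posterior <- function(net, target, evidence = list()) {
  evidence <- check_evidence(net, evidence)
  if (target %in% names(evidence)) abort("`target` must not appear in `evidence`")
  nodes <- bn_nodes(net)
  if (length(nodes) > 15) abort("enumeration is limited to 15 nodes")
  sizes <- vapply(net$variables, length, integer(1))
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE))
  joint <- rep(1, nrow(grid))
  for (v in nodes) {
    cp <- net$cpts[[v]]
    idx <- grid[, c(v, cp$parents), drop = FALSE]
    joint <- joint * array(cp$prob, dim = f_sizes(cpt_factor(net, v)))[idx]
  }
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) {
    keep <- keep & grid[, v] == match(evidence[[v]], bn_levels(net, v))
  }
  tot <- sum(joint[keep])
  if (tot <= 0) {
    abort("zero-probability evidence: the observed evidence set has probability 0 under the network",
          class = "metsbn_zero_evidence")
  }
  p <- vapply(seq_along(bn_levels(net, target)), function(k) {
    sum(joint[keep & grid[, target] == k])
  }, numeric(1)) / tot
  tibble(level = bn_levels(net, target), probability = p)
}

#' Causal reasoning: factor evidence, outcome posterior
#'
#' For each listed factor and each of its levels, instantiates that single
#' level as hard evidence and records the posterior distribution of the
#' outcome next to its no-evidence prior. This is the "cause to effect"
#' reading of the network: how much does fixing a risk factor move the
#' outcome?
#'
#' @param net A valid `bnet`.
#' @param outcome Outcome variable name.
#' @param factors Character vector of factor variables (not containing the
#'   outcome); defaults to all other variables.
#' @return A tibble of class `bn_reasoning` with columns `mode`,
#'   `variable`, `evidence_level`, `outcome_level`, `prior`, `posterior`,
#'   `delta`. Posteriors sum to 1 within each evidence row set.
#' @export
causal_reasoning <- function(net, outcome, factors = setdiff(bn_nodes(net), outcome)) {
  if (outcome %in% factors) abort("`outcome` must not appear in `factors`")
  prior <- ve_query(net, outcome)
  out <- purrr::map_dfr(factors, function(f) {
    purrr::map_dfr(bn_levels(net, f), function(lv) {
      post <- ve_query(net, outcome, setNames(list(lv), f))
      tibble(
        mode = "causal", variable = f, evidence_level = lv,
        outcome_level = names(post),
        prior = unname(prior), posterior = unname(post),
        delta = unname(post - prior)
      )
    })
  })
  class(out) <- c("bn_reasoning", class(out))
  out
}

#' Evidential reasoning: outcome evidence, factor posteriors
#'
#' Conditions on an observed outcome level and reports each factor's
#' posterior distribution next to its prior, with a direction marker
#' (up/down arrow) — the layout used to read off which risk factors are
#' over-represented among, say, subjects who progressed. Equivalent to
#' Bayes inversion of [causal_reasoning()].
#'
#' @inheritParams causal_reasoning
#' @param outcome_level The outcome level observed as evidence.
#' @return A tibble of class `bn_reasoning` with columns `mode`,
#'   `outcome_level`, `variable`, `level`, `prior`, `posterior`, `delta`,
#'   `direction`.
#' @export
evidential_reasoning <- function(net, outcome, outcome_level,
                                 factors = setdiff(bn_nodes(net), outcome)) {
  if (outcome %in% factors) abort("`outcome` must not appear in `factors`")
  if (!outcome_level %in% bn_levels(net, outcome)) {
    abort(paste0("'", outcome_level, "' is not a level of '", outcome, "'"))
  }
  ev <- setNames(list(outcome_level), outcome)
  out <- purrr::map_dfr(factors, function(f) {
    prior <- ve_query(net, f)
    post <- ve_query(net, f, ev)
    tibble(
      mode = "evidential", outcome_level = outcome_level, variable = f,
      level = names(post), prior = unname(prior), posterior = unname(post),
      delta = unname(post - prior),
      direction = dplyr::case_when(
        post - prior > 1e-12 ~ "↑",
        post - prior < -1e-12 ~ "↓",
        TRUE ~ "="
      )
    )
  })
  class(out) <- c("bn_reasoning", class(out))
  out
}

#' Plot a reasoning table
#'
#' Dodged bar chart of prior vs posterior per level, faceted by variable.
#'
#' @param object A `bn_reasoning` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_reasoning <- function(object, ...) {
  lev_col <- if ("level" %in% colnames(object)) "level" else "outcome_level"
  facet_col <- if (object$mode[1] == "causal") "evidence_level" else "variable"
  df <- object |>
    tidyr::pivot_longer(c("prior", "posterior"),
                        names_to = "quantity", values_to = "probability") |>
    mutate(quantity = factor(.data$quantity, c("prior", "posterior")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[lev_col]],
                                   y = .data$probability,
                                   fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(c("variable", facet_col), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "probability", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap arc strengths
#'
#' @param object A `bn_strength` tibble from [bootstrap_arc_strengths()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bn_strength <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$to, y = .data$from,
                                       fill = .data$strength)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$direction)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "to", y = "from", fill = "strength") +
    ggplot2::theme_minimal()
}
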