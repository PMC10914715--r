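# ---- internal scoring on integer-coded data --------------------------------

# local BIC for one family: sum_jk N_ijk log(N_ijk / N_ij) - log(N)/2 * q(r-1)
local_bic <- function(mat, child, parents, nlev, n_pen) {
  counts <- family_counts(mat, child, parents, nlev)
  r <- nlev[[child]]
  q <- length(counts) / r
  m <- matrix(counts, nrow = r)
  nij <- colSums(m)
  pos <- m > 0
  ll <- sum(m[pos] * log(m[pos] / rep(nij, each = r)[pos]))
  ll - log(n_pen) / 2 * q * (r - 1)
}

# scores cached per (node, sorted parent set) within one search
make_score_cache <- function(mat, nlev, n_pen) {
  cache <- new.env(parent = emptyenv())
  function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    s <- local_bic(mat, child, parents, nlev, n_pen)
    cache[[key]] <- s
    s
  }
}

# is `to` reachable from `from` in adjacency matrix A (logical, A[i,j]: i->j)?
reachable <- function(A, from, to) {
  seen <- rep(FALSE, nrow(A))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier) > 0) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0)
    nxt <- nxt[!seen[nxt]]
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen[to]
}

#' BIC network score for discrete data
#'
#' Decomposable Bayesian Information Criterion for a categorical data set
#' under a DAG: the multinomial log-likelihood of each node given its
#' parents minus \eqn{\frac{\log N}{2} \sum_i q_i (r_i - 1)}. Higher is
#' better; `0 log 0` is taken as 0.
#'
#' @param data Data frame of categorical columns.
#' @param dag Data frame of arcs (`from`, `to`); zero rows for the empty
#'   graph.
#' @param levels Optional named list of declared levels.
#' @return A single number.
#' @export
bic_score <- function(data, dag, levels = NULL) {
  cd <- code_data(data, levels)
  pa <- dag_parents(dag, colnames(cd$mat))
  n_pen <- nrow(cd$mat)
  sum(vapply(colnames(cd$mat), function(v) {
    local_bic(cd$mat, v, pa[[v]], cd$nlev, n_pen)
  }, numeric(1)))
}

check_constraints <- function(whitelist, blacklist, nodes) {
  norm <- function(x) {
    if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
      return(tibble(from = character(), to = character()))
    }
    x <- as.data.frame(x)
    stopifnot(all(c("from", "to") %in% colnames(x)))
    as_tibble(x[, c("from", "to")])
  }
  wl <- norm(whitelist); bl <- norm(blacklist)
  unknown <- setdiff(unique(c(wl$from, wl$to, bl$from, bl$to)), nodes)
  if (length(unknown) > 0) {
    abort(paste0("constraints name unknown node(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(wl$from == wl$to) || any(bl$from == bl$to)) {
    abort("constraints must not contain self-loops")
  }
  both <- inner_join(wl, bl, by = c("from", "to"))
  if (nrow(both) > 0) {
    abort(paste0("arc(s) both whitelisted and blacklisted: ",
                 paste(both$from, both$to, sep = "->", collapse = ", ")))
  }
  if (is.null(topo_order(dag_parents_noabort(wl, nodes)))) {
    abort("whitelist arcs are jointly cyclic")
  }
  list(wl = wl, bl = bl)
}

dag_parents_noabort <- function(dag, nodes) {
  pa <- lapply(nodes, function(v) {
    if (nrow(dag) == 0) character() else sort(dag$from[dag$to == v])
  })
  names(pa) <- nodes
  pa
}

hill_climb_coded <- function(mat, nlev, wl, bl, max_iter = 200L) {
  nodes <- colnames(mat)
  n <- length(nodes)
  score_fn <- make_score_cache(mat, nlev, max(nrow(mat), 1))
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (t in seq_len(nrow(wl))) {
    A[wl$from[t], wl$to[t]] <- TRUE
  }
  B <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (t in seq_len(nrow(bl))) {
    B[bl$from[t], bl$to[t]] <- TRUE
  }
  W <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (t in seq_len(nrow(wl))) {
    W[wl$from[t], wl$to[t]] <- TRUE
  }
  node_score <- vapply(nodes, function(v) score_fn(v, nodes[A[, v]]), numeric(1))
  ord <- order(nodes)
  # score-equivalent moves (e.g. the two orientations of a fresh arc) differ
  # only by floating-point noise; treating deltas within `tie_tol` as equal
  # lets the lexicographic enumeration order break the tie deterministically
  tie_tol <- 1e-6
  for (iter in seq_len(max_iter)) {
    best <- list(delta = tie_tol, move = NULL)
    for (ui in ord) {
      for (vi in ord) {
        if (ui == vi) next
        u <- nodes[ui]; v <- nodes[vi]
        if (!A[u, v]) {
          # add u -> v
          if (B[u, v] || reachable(A, which(nodes == v), which(nodes == u))) next
          d <- score_fn(v, c(nodes[A[, v]], u)) - node_score[v]
          if (d > best$delta + tie_tol) best <- list(delta = d, move = c("add", u, v))
        } else {
          # delete u -> v
          if (!W[u, v]) {
            d <- score_fn(v, setdiff(nodes[A[, v]], u)) - node_score[v]
            if (d > best$delta + tie_tol) best <- list(delta = d, move = c("delete", u, v))
          }
          # reverse u -> v
          if (!W[u, v] && !B[v, u]) {
            A[u, v] <- FALSE
            cyc <- reachable(A, which(nodes == u), which(nodes == v))
            A[u, v] <- TRUE
            if (!cyc) {
              d <- (score_fn(v, setdiff(nodes[A[, v]], u)) - node_score[v]) +
                (score_fn(u, c(nodes[A[, u]], v)) - node_score[u])
              if (d > best$delta + tie_tol) best <- list(delta = d, move = c("reverse", u, v))
            }
          }
        }
      }
    }
    if (is.null(best$move)) break
    mv <- best$move
    u <- mv[2]; v <- mv[3]
    if (mv[1] == "add") {
      A[u, v] <- TRUE
      node_score[v] <- score_fn(v, nodes[A[, v]])
    } else if (mv[1] == "delete") {
      A[u, v] <- FALSE
      node_score[v] <- score_fn(v, nodes[A[, v]])
    } else {
      A[u, v] <- FALSE
      A[v, u] <- TRUE
      node_score[v] <- score_fn(v, nodes[A[, v]])
      node_score[u] <- score_fn(u, nodes[A[, u]])
    }
  }
  idx <- which(A, arr.ind = TRUE)
  edges <- tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]])
  edges <- arrange(edges, .data$from, .data$to)
  attr(edges, "score") <- sum(node_score)
  edges
}

#' Greedy hill-climbing structure search under arc constraints
#'
#' Learns a DAG by greedy search over single-arc moves (add, delete,
#' reverse) scored with [bic_score()], starting from the whitelist-only
#' graph. Blacklisted arcs are never added, whitelisted arcs never removed
#' or reversed, and no move may create a cycle. The search stops at a
#' local optimum (no move improves the score by more than `1e-9`).
#'
#' The search is fully deterministic: among equal-score moves the first in
#' lexicographic order of (from, to, move type) is taken, so repeated runs
#' on the same data and constraints return the same graph.
#'
#' @param data Data frame of categorical columns; every column is a node.
#' @param whitelist,blacklist Optional data frames of arcs (`from`, `to`):
#'   required resp. forbidden. They must be disjoint and the whitelist
#'   jointly acyclic.
#' @param levels Optional named list of declared levels.
#' @param max_iter Maximum number of accepted moves.
#' @return A tibble of arcs (`from`, `to`) with the final network score in
#'   `attr(, "score")`.
#' @export
hill_climb <- function(data, whitelist = NULL, blacklist = NULL,
                       levels = NULL, max_iter = 200L) {
  cd <- code_data(data, levels)
  if (nrow(cd$mat) == 0) abort("`data` must contain at least one row")
  cons <- check_constraints(whitelist, blacklist, colnames(cd$mat))
  hill_climb_coded(cd$mat, cd$nlev, cons$wl, cons$bl, max_iter)
}

#' Bootstrap arc strengths for model averaging
#'
#' Draws `B` nonparametric bootstrap resamples of the rows (same size,
#' with replacement), runs [hill_climb()] on each, and aggregates, per
#' node pair, the *strength* (fraction of bootstrap networks containing
#' the arc in either direction) and the *direction* (fraction of those
#' supporting this orientation). Replicate seeds are derived from the
#' master seed by a counter, so increasing `B` extends the replicate
#' sequence without changing earlier resamples.
#'
#' @inheritParams hill_climb
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed Master integer seed.
#' @return A tibble of class `bn_strength` with columns `from`, `to`,
#'   `strength`, `direction`, one row per ordered pair observed in at
#'   least one replicate.
#' @seealso [averaged_network()]
#' @export
bootstrap_arc_strengths <- function(data, B, seed, whitelist = NULL,
                                    blacklist = NULL, levels = NULL,
                                    max_iter = 200L) {
  stopifnot(is.numeric(B), length(B) == 1, B >= 1)
  cd <- code_data(data, levels)
  nodes <- colnames(cd$mat)
  cons <- check_constraints(whitelist, blacklist, nodes)
  n <- nrow(cd$mat)
  hits <- matrix(0, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (b in seq_len(B)) {
    set.seed(as.integer(seed) + b)
    idx <- sample.int(n, n, replace = TRUE)
    edges <- hill_climb_coded(cd$mat[idx, , drop = FALSE], cd$nlev,
                              cons$wl, cons$bl, max_iter)
    for (t in seq_len(nrow(edges))) {
      hits[edges$from[t], edges$to[t]] <- hits[edges$from[t], edges$to[t]] + 1
    }
  }
  pairs <- expand_grid(from = nodes, to = nodes) |> filter(.data$from != .data$to)
  out <- pairs |>
    mutate(
      n_dir = purrr::map2_dbl(.data$from, .data$to, ~ hits[.x, .y]),
      n_pair = purrr::map2_dbl(.data$from, .data$to, ~ hits[.x, .y] + hits[.y, .x]),
      strength = .data$n_pair / B,
      direction = ifelse(.data$n_pair > 0, .data$n_dir / .data$n_pair, 0)
    ) |>
    filter(.data$n_pair > 0) |>
    select("from", "to", "strength", "direction") |>
    arrange(.data$from, .data$to)
  class(out) <- c("bn_strength", class(out))
  out
}

#' Model-averaged network from bootstrap arc strengths
#'
#' Keeps arcs whose undirected strength meets `strength_threshold`
#' (inclusive), oriented in the direction whose directional fraction
#' exceeds `direction_threshold`; an exact directional tie is broken
#' towards the lexicographically smaller `from` node. The result is forced
#' acyclic: retained arcs are added in decreasing strength order and any
#' arc that would close a cycle is dropped (i.e. cycle-inducing arcs are
#' discarded in increasing strength order).
#'
#' @param strengths A `bn_strength` tibble from
#'   [bootstrap_arc_strengths()].
#' @param strength_threshold Minimum undirected strength, in (0, 1\];
#'   default 0.85.
#' @param direction_threshold Directional fraction an orientation must
#'   exceed, in (0, 1\]; default 0.5.
#' @return A tibble of arcs (`from`, `to`).
#' @export
averaged_network <- function(strengths, strength_threshold = 0.85,
                             direction_threshold = 0.5) {
  stopifnot(strength_threshold > 0, strength_threshold <= 1,
            direction_threshold > 0, direction_threshold <= 1)
  st <- as_tibble(strengths)
  st <- st |>
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    filter(.data$strength >= strength_threshold)
  if (nrow(st) == 0) return(tibble(from = character(), to = character()))
  pairs <- st |> distinct(.data$a, .data$b, .keep_all = TRUE)
  oriented <- purrr::map_dfr(seq_len(nrow(pairs)), function(t) {
    sub <- st |> filter(.data$a == pairs$a[t], .data$b == pairs$b[t])
    win <- sub |> filter(.data$direction > direction_threshold)
    if (nrow(win) == 0) {
      # exact tie (e.g. both directions at 0.5): lexicographic from-node
      win <- sub |> arrange(.data$from) |> slice(1)
    }
    win |> arrange(desc(.data$direction)) |> slice(1) |>
      select("from", "to", "strength")
  })
  oriented <- oriented |> arrange(desc(.data$strength), .data$from, .data$to)
  nodes <- sort(unique(c(oriented$from, oriented$to)))
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  keep <- logical(nrow(oriented))
  for (t in seq_len(nrow(oriented))) {
    u <- oriented$from[t]; v <- oriented$to[t]
    if (!reachable(A, match(v, nodes), match(u, nodes))) {
      A[u, v] <- TRUE
      keep[t] <- TRUE
    }
  }
  oriented[keep, c("from", "to")] |> arrange(.data$from, .data$to)
}
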