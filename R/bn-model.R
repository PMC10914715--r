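#' Construct a discrete Bayesian network
#'
#' A `bnet` bundles a set of categorical variables, a directed acyclic graph
#' (DAG), and one conditional probability table (CPT) per node. The DAG is
#' implied by the CPT parent sets, so structure and parameters can never
#' drift apart.
#'
#' CPT probabilities may be supplied either as the internal array layout
#' (child dimension first, then parents in declared order) or, more
#' conveniently, as a matrix with one row per parent-level combination and
#' one column per child level — the layout of a printed conditional
#' probability table. Parent-level combinations are enumerated in row-major
#' order of the parents' declared level orders (last parent varies fastest);
#' this ordering is part of the serialization contract.
#'
#' Rows whose probabilities sum to within `1e-6` of 1 are silently
#' renormalized (printed tables are typically rounded to 2 decimals and can
#' be off by a rounding residue); rows further off are rejected.
#'
#' @param variables Named list: variable name -> character vector of level
#'   labels (at least 2, unique, order fixed).
#' @param cpts Named list keyed by child variable; each element is a list
#'   with `parents` (character vector, possibly empty) and `prob` (numeric
#'   vector for a root node, or a q x r matrix / internal array otherwise).
#' @param check If `TRUE` (default) the constructor validates the network
#'   and applies the row-sum policy; `check = FALSE` builds the object
#'   verbatim (useful to feed [validate_bnet()] deliberately broken nets).
#' @return An object of class `bnet`.
#' @seealso [validate_bnet()], [joint_probability()], [bn_query()]
#' @examples
#' net <- bnet(
#'   variables = list(a = c("no", "yes"), b = c("no", "yes")),
#'   cpts = list(
#'     a = list(parents = character(), prob = c(0.7, 0.3)),
#'     b = list(parents = "a", prob = rbind(c(0.9, 0.1), c(0.4, 0.6)))
#'   )
#' )
#' joint_probability(net, c(a = "yes", b = "yes"))
#' @export
bnet <- function(variables, cpts, check = TRUE) {
  stopifnot(is.list(variables), is.list(cpts))
  if (is.null(names(variables)) || any(names(variables) == "")) {
    abort("`variables` must be a fully named list")
  }
  cpts <- cpts[names(variables)[names(variables) %in% names(cpts)]]
  built <- lapply(names(variables), function(v) {
    spec <- cpts[[v]]
    if (is.null(spec)) abort(paste0("no CPT supplied for node '", v, "'"))
    parents <- spec$parents %||% character()
    build_cpt(v, parents, spec$prob, variables, check = check)
  })
  names(built) <- names(variables)
  net <- new_bnet(variables, built)
  if (check) {
    bad <- validate_bnet(net)
    if (nrow(bad) > 0) {
      abort(paste0("invalid network:\n", paste0("- ", bad$violation, collapse = "\n")))
    }
  }
  net
}

new_bnet <- function(variables, cpts) {
  edges <- purrr::map_dfr(cpts, function(cp) {
    if (length(cp$parents) == 0) return(tibble(from = character(), to = character()))
    tibble(from = cp$parents, to = cp$child)
  })
  edges <- arrange(edges, .data$from, .data$to)
  structure(list(variables = variables, cpts = cpts, edges = edges),
            class = "bnet")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parent-level combinations in serialization order (last parent fastest);
# integer matrix, one column per parent in declared order
ser_grid <- function(sizes) {
  if (length(sizes) == 0) return(matrix(integer(), nrow = 1, ncol = 0))
  g <- expand.grid(lapply(rev(sizes), seq_len), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g[, rev(seq_along(sizes)), drop = FALSE])
}

# column-major linear index of a parent combination in the internal array
combo_lin <- function(idx, sizes) {
  if (length(sizes) == 0) return(rep(1L, nrow(idx)))
  mult <- cumprod(c(1, sizes[-length(sizes)]))
  as.integer(1 + (idx - 1) %*% mult)
}

build_cpt <- function(child, parents, prob, variables, check = TRUE) {
  levs <- variables[[child]]
  r <- length(levs)
  psizes <- vapply(parents, function(p) length(variables[[p]] %||% character()),
                   integer(1))
  q <- prod(psizes)
  if (is.matrix(prob) && length(parents) > 0) {
    if (nrow(prob) != q || ncol(prob) != r) {
      abort(paste0("CPT for '", child, "' must be ", q, " x ", r))
    }
    arr <- array(0, dim = c(r, psizes))
    lin <- combo_lin(ser_grid(psizes), psizes)
    m <- matrix(arr, nrow = r)
    for (t in seq_len(q)) m[, lin[t]] <- prob[t, ]
    arr <- array(m, dim = c(r, psizes))
  } else {
    arr <- array(as.numeric(prob), dim = c(r, psizes))
    if (length(prob) != r * q) {
      abort(paste0("CPT for '", child, "' has ", length(prob),
                   " entries; expected ", r * q))
    }
  }
  dimnames(arr) <- c(list(levs), unname(lapply(parents, function(p) variables[[p]])))
  if (check) arr <- normalize_rows(arr, child, r)
  list(child = child, parents = parents, prob = arr)
}

normalize_rows <- function(arr, child, r) {
  m <- matrix(arr, nrow = r)
  sums <- colSums(m)
  off <- abs(sums - 1)
  if (any(off > 1e-6)) {
    j <- which.max(off)
    abort(paste0("CPT row ", j, " of node '", child, "' sums to ",
                 format(sums[j], digits = 10), " (tolerance 1e-6)"))
  }
  # rows already within the validation tolerance are left untouched so that
  # serialization round trips reproduce probabilities bit-for-bit
  fix <- off > 1e-9
  m[, fix] <- sweep(m[, fix, drop = FALSE], 2, sums[fix], "/")
  array(m, dim = dim(arr), dimnames = dimnames(arr))
}

bn_nodes <- function(net) names(net$variables)
bn_levels <- function(net, v) net$variables[[v]]
bn_parents <- function(net, v) net$cpts[[v]]$parents

# topological order of a parent-set list; NULL if cyclic
topo_order <- function(parents) {
  nodes <- names(parents)
  placed <- character(0)
  repeat {
    ready <- sort(setdiff(
      nodes[vapply(nodes, function(v) all(parents[[v]] %in% placed), logical(1))],
      placed))
    if (length(ready) == 0) break
    placed <- c(placed, ready[1])
    if (length(placed) == length(nodes)) return(placed)
  }
  NULL
}

#' Validate a discrete Bayesian network
#'
#' Checks every structural and numerical invariant of a [bnet()]: unique
#' level labels, CPT dimensions consistent with the declared parent sets,
#' parent names that exist, no self-loops, acyclicity, probability entries
#' in \[0, 1\], and CPT rows summing to 1 (tolerance `1e-9`). Violations are
#' returned, not raised, so broken networks can be inspected.
#'
#' @param net A `bnet` (possibly built with `check = FALSE`).
#' @return A tibble with one column, `violation`; zero rows means the
#'   network satisfies all invariants.
#' @export
validate_bnet <- function(net) {
  v <- character(0)
  vars <- net$variables
  for (nm in names(vars)) {
    if (length(vars[[nm]]) < 2) {
      v <- c(v, paste0("variable '", nm, "' has fewer than 2 levels"))
    }
    if (anyDuplicated(vars[[nm]])) {
      v <- c(v, paste0("variable '", nm, "' has duplicated level labels"))
    }
  }
  for (nm in names(vars)) {
    cp <- net$cpts[[nm]]
    if (is.null(cp)) {
      v <- c(v, paste0("node '", nm, "' has no CPT"))
      next
    }
    unknown <- setdiff(cp$parents, names(vars))
    if (length(unknown) > 0) {
      v <- c(v, paste0("node '", nm, "' has undeclared parent(s): ",
                       paste(unknown, collapse = ", ")))
      next
    }
    if (nm %in% cp$parents) {
      v <- c(v, paste0("node '", nm, "' is its own parent (self-loop)"))
    }
    want <- c(length(vars[[nm]]), vapply(cp$parents, function(p) length(vars[[p]]), integer(1)))
    got <- dim(cp$prob) %||% length(cp$prob)
    if (!identical(as.integer(got), as.integer(want))) {
      v <- c(v, paste0("CPT of node '", nm, "' has dimensions (",
                       paste(got, collapse = ", "), "); expected (",
                       paste(want, collapse = ", "), ")"))
      next
    }
    m <- matrix(cp$prob, nrow = length(vars[[nm]]))
    if (anyNA(m) || any(m < 0) || any(m > 1)) {
      v <- c(v, paste0("CPT of node '", nm, "' has entries outside [0, 1]"))
    }
    sums <- colSums(m)
    bad <- which(abs(sums - 1) > 1e-9)
    for (j in bad) {
      v <- c(v, paste0("CPT row ", j, " of node '", nm, "' sums to ",
                       format(sums[j], digits = 10), ", not 1"))
    }
  }
  parents <- lapply(net$cpts, function(cp) intersect(cp$parents, names(vars)))
  names(parents) <- names(net$cpts)
  if (length(parents) == length(vars) && is.null(topo_order(parents))) {
    v <- c(v, "the graph implied by the CPT parent sets contains a directed cycle")
  }
  tibble(violation = v)
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorization \eqn{\prod_i P(x_i \mid pa(x_i))} from the
#' network's CPTs for one complete assignment of every variable.
#'
#' @param net A valid `bnet`.
#' @param assignment Named character vector or list mapping every variable
#'   to one of its declared levels.
#' @return A single probability in \[0, 1\].
#' @export
joint_probability <- function(net, assignment) {
  assignment <- as.list(assignment)
  missing <- setdiff(bn_nodes(net), names(assignment))
  if (length(missing) > 0) {
    abort(paste0("assignment is missing variable(s): ",
                 paste(missing, collapse = ", ")))
  }
  idx <- vapply(bn_nodes(net), function(v) {
    i <- match(assignment[[v]], bn_levels(net, v))
    if (is.na(i)) {
      abort(paste0("'", assignment[[v]], "' is not a level of variable '", v, "'"))
    }
    i
  }, integer(1))
  prod(vapply(bn_nodes(net), function(v) {
    cp <- net$cpts[[v]]
    pos <- c(idx[[v]], idx[cp$parents])
    do.call(`[`, c(list(cp$prob), as.list(pos)))
  }, numeric(1)))
}

#' @export
print.bnet <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$variables), "nodes,",
      nrow(x$edges), "arcs\n")
  for (v in bn_nodes(x)) {
    pa <- bn_parents(x, v)
    cat("  ", v, " (", paste(bn_levels(x, v), collapse = "/"), ")",
        if (length(pa)) paste0("  <- ", paste(pa, collapse = ", ")) else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.bnet <- function(x, ...) {
  purrr::map_dfr(x$cpts, function(cp) {
    sizes <- vapply(cp$parents, function(p) length(x$variables[[p]]), integer(1))
    g <- ser_grid(sizes)
    lin <- combo_lin(g, sizes)
    m <- matrix(cp$prob, nrow = length(x$variables[[cp$child]]))
    rows <- purrr::map_dfr(seq_len(nrow(g)), function(t) {
      tibble(
        node = cp$child,
        parent_config = if (length(cp$parents) == 0) "" else
          paste(vapply(seq_along(cp$parents), function(j) {
            paste0(cp$parents[j], "=", x$variables[[cp$parents[j]]][g[t, j]])
          }, character(1)), collapse = ", "),
        level = x$variables[[cp$child]],
        probability = m[, lin[t]]
      )
    })
    rows
  })
}

#' @export
glance.bnet <- function(x, ...) {
  npar <- sum(vapply(x$cpts, function(cp) {
    r <- length(x$variables[[cp$child]])
    q <- prod(vapply(cp$parents, function(p) length(x$variables[[p]]), integer(1)))
    q * (r - 1)
  }, numeric(1)))
  tibble(
    nodes = length(x$variables),
    arcs = nrow(x$edges),
    parameters = npar
  )
}
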