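# integer-code a categorical data frame; levels from factors (order kept),
# from a supplied `levels` list, or from sorted unique values of character
# columns
code_data <- function(data, levels = NULL) {
  data <- as.data.frame(data)
  levs <- list()
  mat <- matrix(NA_integer_, nrow = nrow(data), ncol = ncol(data),
                dimnames = list(NULL, colnames(data)))
  for (j in seq_along(data)) {
    nm <- colnames(data)[j]
    col <- data[[j]]
    if (!is.null(levels) && !is.null(levels[[nm]])) {
      lv <- levels[[nm]]
      vals <- as.character(col)
      code <- match(vals, lv)
      bad <- which(!is.na(vals) & is.na(code))
      if (length(bad) > 0) {
        abort(paste0("undeclared level '", vals[bad[1]], "' in column '", nm,
                     "', row ", bad[1]))
      }
    } else if (is.factor(col)) {
      lv <- base::levels(col)
      code <- as.integer(col)
    } else {
      vals <- as.character(col)
      lv <- sort(unique(vals[!is.na(vals)]))
      code <- match(vals, lv)
    }
    levs[[nm]] <- lv
    mat[, j] <- code
  }
  list(mat = mat, levels = levs, nlev = vapply(levs, length, integer(1)))
}

dag_parents <- function(dag, nodes) {
  dag <- as.data.frame(dag)
  if (nrow(dag) > 0) {
    stopifnot(all(c("from", "to") %in% colnames(dag)))
    unknown <- setdiff(unique(c(dag$from, dag$to)), nodes)
    if (length(unknown) > 0) {
      abort(paste0("DAG names node(s) absent from the data: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  pa <- lapply(nodes, function(v) {
    if (nrow(dag) == 0) character() else sort(dag$from[dag$to == v])
  })
  names(pa) <- nodes
  if (is.null(topo_order(pa))) abort("the supplied graph contains a directed cycle")
  pa
}

# counts for one node family; NA rows (within the family) dropped
family_counts <- function(mat, child, parents, nlev) {
  r <- nlev[[child]]
  sizes <- nlev[parents]
  q <- prod(sizes)
  cols <- mat[, c(child, parents), drop = FALSE]
  ok <- !is.na(cols[, 1])
  if (ncol(cols) > 1) ok <- ok & rowSums(is.na(cols[, -1, drop = FALSE])) == 0
  cols <- cols[ok, , drop = FALSE]
  cell <- cols[, 1]
  if (length(parents) > 0) {
    mult <- r * cumprod(c(1, sizes[-length(sizes)]))
    cell <- cell + (cols[, -1, drop = FALSE] - 1L) %*% mult
  }
  counts <- tabulate(cell, nbins = r * q)
  array(counts, dim = c(r, sizes))
}

#' Tabulate per-family counts for CPT estimation
#'
#' For each node, counts the occurrences of every (child level,
#' parent-level combination) cell. Rows with a missing value anywhere in a
#' node's family (the node plus its parents) are excluded from that
#' family's table only (`complete_case = "family"`, the default) or rows
#' with any missing value are excluded everywhere
#' (`complete_case = "row"`).
#'
#' @param data Data frame of categorical columns (factors preferred;
#'   character columns use sorted unique values as levels).
#' @param dag Data frame of arcs with columns `from`, `to` (may have zero
#'   rows for the empty graph).
#' @param levels Optional named list of declared levels; values outside a
#'   declared set raise an error naming the row and column.
#' @param complete_case `"family"` or `"row"`.
#' @return Named list, one element per node: `child`, `parents`, `counts`
#'   (array, child dimension first) and `n` (total count).
#' @export
tabulate_counts <- function(data, dag, levels = NULL,
                            complete_case = c("family", "row")) {
  complete_case <- match.arg(complete_case)
  cd <- code_data(data, levels)
  if (complete_case == "row" && nrow(cd$mat) > 0) {
    cd$mat <- cd$mat[rowSums(is.na(cd$mat)) == 0, , drop = FALSE]
  }
  nodes <- colnames(cd$mat)
  pa <- dag_parents(dag, nodes)
  out <- lapply(nodes, function(v) {
    counts <- family_counts(cd$mat, v, pa[[v]], cd$nlev)
    dimnames(counts) <- c(list(cd$levels[[v]]),
                          unname(cd$levels[pa[[v]]]))
    list(child = v, parents = pa[[v]], counts = counts, n = sum(counts))
  })
  names(out) <- nodes
  out
}

#' Fit conditional probability tables by Dirichlet posterior mean
#'
#' Given a fixed DAG and complete categorical data, estimates each CPT
#' entry as the posterior mean under a uniform Dirichlet prior (BDeu-style)
#' with imaginary sample size `iss`:
#' \deqn{\hat\theta_{ijk} = \frac{N_{ijk} + \alpha_{ijk}}{N_{ij} + \sum_k \alpha_{ijk}},
#'   \qquad \alpha_{ijk} = \frac{iss}{r_i\, q_i},}
#' where \eqn{N_{ijk}} counts child level \eqn{k} under parent combination
#' \eqn{j}, \eqn{r_i} is the number of child levels and \eqn{q_i} the
#' number of parent combinations. Parent combinations never observed
#' (\eqn{N_{ij} = 0}) fall back to the uniform prior mean; every estimate
#' is strictly inside (0, 1) for `iss > 0`, and `iss` close to 0 recovers
#' maximum-likelihood proportions wherever data exist.
#'
#' @inheritParams tabulate_counts
#' @param iss Imaginary sample size of the Dirichlet prior (default 1).
#' @return A fitted [bnet()].
#' @examples
#' d <- data.frame(a = factor(c("yes", "yes", "yes", "no"), c("no", "yes")))
#' fit_cpts(d, dag = data.frame(from = character(), to = character()))
#' @export
fit_cpts <- function(data, dag, iss = 1, levels = NULL,
                     complete_case = c("family", "row")) {
  stopifnot(is.numeric(iss), length(iss) == 1, iss >= 0)
  tabs <- tabulate_counts(data, dag, levels = levels,
                          complete_case = complete_case)
  variables <- lapply(tabs, function(tb) dimnames(tb$counts)[[1]])
  cpts <- lapply(tabs, function(tb) {
    r <- dim(tb$counts)[1]
    q <- prod(dim(tb$counts)) / r
    alpha <- iss / (r * q)
    m <- matrix(tb$counts, nrow = r)
    nij <- colSums(m)
    denom <- nij + r * alpha
    theta <- if (iss == 0) {
      sw <- sweep(m, 2, pmax(nij, 1), "/")
      sw[, nij == 0] <- 1 / r
      sw
    } else {
      sweep(m + alpha, 2, denom, "/")
    }
    # plain column-major vector = the internal array layout (child fastest)
    list(parents = tb$parents, prob = as.numeric(theta))
  })
  bnet(variables, cpts)
}
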