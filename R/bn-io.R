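#' Write a network to the package's JSON dialect
#'
#' Serializes a [bnet()] with deterministic ordering: variables in
#' declaration order, edges sorted lexicographically, and CPT rows in
#' row-major order of the parents' declared level orders (last parent
#' varies fastest). Probabilities are written at full double precision,
#' so a write/read round trip reproduces [joint_probability()]
#' bit-for-bit.
#'
#' Top-level fields: `variables` (name, levels), `edges` (from, to) and
#' `cpts` (child, parents, rows with the parent-level combination and the
#' probability vector over the child's levels).
#'
#' @param net A valid `bnet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_bnet_json()], [write_bnet_bif()]
#' @export
write_bnet_json <- function(net, path) {
  obj <- list(
    variables = lapply(bn_nodes(net), function(v) {
      list(name = v, levels = as.list(bn_levels(net, v)))
    }),
    edges = purrr::pmap(net$edges, function(from, to) list(from = from, to = to)),
    cpts = lapply(bn_nodes(net), function(v) {
      cp <- net$cpts[[v]]
      sizes <- vapply(cp$parents, function(p) length(bn_levels(net, p)), integer(1))
      g <- ser_grid(sizes)
      lin <- combo_lin(g, sizes)
      m <- matrix(cp$prob, nrow = length(bn_levels(net, v)))
      rows <- lapply(seq_len(nrow(g)), function(t) {
        list(
          parents = as.list(vapply(seq_along(cp$parents), function(j) {
            bn_levels(net, cp$parents[j])[g[t, j]]
          }, character(1))),
          p = m[, lin[t]]
        )
      })
      list(child = v, parents = as.list(cp$parents), rows = rows)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read a network from the package's JSON dialect
#'
#' @param path A file written by [write_bnet_json()].
#' @return A validated `bnet`.
#' @export
read_bnet_json <- function(path) {
  obj <- jsonlite::read_json(path)
  variables <- setNames(
    lapply(obj$variables, function(v) as.character(unlist(v$levels))),
    vapply(obj$variables, function(v) v$name, character(1))
  )
  cpts <- setNames(lapply(obj$cpts, function(cp) {
    parents <- as.character(unlist(cp$parents))
    r <- length(variables[[cp$child]])
    prob <- do.call(rbind, lapply(cp$rows, function(row) as.numeric(unlist(row$p))))
    if (length(parents) == 0) {
      list(parents = character(), prob = as.numeric(prob[1, ]))
    } else {
      list(parents = parents, prob = prob)
    }
  }), vapply(obj$cpts, function(cp) cp$child, character(1)))
  bnet(variables, cpts)
}

#' Export a network in Bayesian Interchange Format (BIF)
#'
#' Writes the standard plain-text BIF representation for interoperability
#' with other Bayesian-network software. Import is not provided; the JSON
#' dialect ([write_bnet_json()]) is the package's round-trip format.
#'
#' @param net A valid `bnet`.
#' @param path Output file path.
#' @param name Network name written to the header.
#' @return `path`, invisibly.
#' @export
write_bnet_bif <- function(net, path, name = "network") {
  fmt <- function(p) sprintf("%.17g", p)
  lines <- c(paste0("network ", name, " {"), "}")
  for (v in bn_nodes(net)) {
    levs <- bn_levels(net, v)
    lines <- c(lines,
               paste0("variable ", v, " {"),
               paste0("  type discrete [ ", length(levs), " ] { ",
                      paste(levs, collapse = ", "), " };"),
               "}")
  }
  for (v in bn_nodes(net)) {
    cp <- net$cpts[[v]]
    r <- length(bn_levels(net, v))
    if (length(cp$parents) == 0) {
      lines <- c(lines,
                 paste0("probability ( ", v, " ) {"),
                 paste0("  table ", paste(fmt(as.numeric(cp$prob)), collapse = ", "), ";"),
                 "}")
    } else {
      sizes <- vapply(cp$parents, function(p) length(bn_levels(net, p)), integer(1))
      g <- ser_grid(sizes)
      lin <- combo_lin(g, sizes)
      m <- matrix(cp$prob, nrow = r)
      body <- vapply(seq_len(nrow(g)), function(t) {
        combo <- vapply(seq_along(cp$parents), function(j) {
          bn_levels(net, cp$parents[j])[g[t, j]]
        }, character(1))
        paste0("  ( ", paste(combo, collapse = ", "), " ) ",
               paste(fmt(m[, lin[t]]), collapse = ", "), ";")
      }, character(1))
      lines <- c(lines,
                 paste0("probability ( ", v, " | ",
                        paste(cp$parents, collapse = ", "), " ) {"),
                 body,
                 "}")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
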