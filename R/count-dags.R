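# Minimal exact big-integer arithmetic (non-negative, base 1e7 limbs,
# little-endian numeric vectors). Only what Robinson's recurrence needs:
# the counts overflow doubles from 10 nodes on, and no arbitrary-precision
# package is a dependency of this package.

BIG_BASE <- 1e7

big_norm <- function(x) {
  carry <- 0
  out <- numeric(0)
  i <- 1
  while (i <= length(x) || carry > 0) {
    v <- carry + if (i <= length(x)) x[i] else 0
    out[i] <- v %% BIG_BASE
    carry <- (v - out[i]) / BIG_BASE
    i <- i + 1
  }
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_from_num <- function(n) {
  stopifnot(n >= 0, n == floor(n))
  if (n == 0) return(0)
  out <- numeric(0)
  while (n > 0) {
    out <- c(out, n %% BIG_BASE)
    n <- (n - n %% BIG_BASE) / BIG_BASE
  }
  out
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

big_cmp <- function(a, b) {
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

big_sub <- function(a, b) { # requires a >= b
  stopifnot(big_cmp(a, b) >= 0)
  b <- c(b, rep(0, length(a) - length(b)))
  out <- numeric(length(a))
  borrow <- 0
  for (i in seq_along(a)) {
    v <- a[i] - b[i] - borrow
    borrow <- if (v < 0) 1 else 0
    out[i] <- v + borrow * BIG_BASE
  }
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_mul <- function(a, b) {
  # base-1e7 limbs keep every partial sum below 2^53 for the sizes
  # Robinson's recurrence produces at n <= 20
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  big_norm(out)
}

big_pow2 <- function(k) {
  x <- 1
  if (k == 0) return(x)
  for (i in seq_len(k)) x <- big_add(x, x)
  x
}

big_to_chr <- function(x) {
  paste0(format(x[length(x)], scientific = FALSE),
         paste(sprintf("%07.0f", rev(x[-length(x)])), collapse = ""))
}

big_to_value <- function(x) {
  v <- sum(x * BIG_BASE^(seq_along(x) - 1))
  if (v <= 2^53) v else big_to_chr(x)
}

#' Count labeled directed acyclic graphs
#'
#' Number of distinct labeled DAGs on `n` nodes, i.e. the size of the
#' search space a structure-learning algorithm faces, by Robinson's
#' recurrence
#' \deqn{a(n) = \sum_{i=1}^{n} (-1)^{i+1} \binom{n}{i} 2^{i(n-i)} a(n-i),
#'   \quad a(0) = 1.}
#' Computation is exact for all supported `n`: counts beyond the range of
#' double precision (from `n = 10`) are returned as decimal strings.
#'
#' @param n Number of nodes, `0 <= n <= 20`.
#' @return A numeric count when exactly representable as a double,
#'   otherwise a character string with the exact decimal value.
#' @examples
#' count_dags(3) # 25
#' count_dags(4) # 543
#' @export
count_dags <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n != floor(n) || n < 0) {
    abort("`n` must be a single non-negative integer")
  }
  if (n > 20) abort("`n` must be at most 20")
  a <- vector("list", n + 1)
  a[[1]] <- 1 # a(0)
  if (n >= 1) {
    for (m in seq_len(n)) {
      pos <- 0
      neg <- 0
      for (i in seq_len(m)) {
        term <- big_mul(big_from_num(choose(m, i)), big_pow2(i * (m - i)))
        term <- big_mul(term, a[[m - i + 1]])
        if (i %% 2 == 1) pos <- big_add(pos, term) else neg <- big_add(neg, term)
      }
      a[[m + 1]] <- big_sub(pos, neg)
    }
  }
  big_to_value(a[[n + 1]])
}
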