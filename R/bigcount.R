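# Minimal exact non-negative integer arithmetic for sequence-space counts.
# Sequence spaces such as 5^42 exceed 2^53 and cannot be held exactly in a
# double; counts are stored as little-endian limb vectors in base 1e6 so that
# limb products stay well inside exact double range during multiplication.

BIG_BASE <- 1e6

#' Exact big-integer counts
#'
#' `bigcount()` wraps a non-negative integer (given as a double below 2^53,
#' or a raw limb vector) as an exact arbitrary-precision count. Only the
#' operations needed for sequence-space arithmetic are provided:
#' multiplication, integer powers, equality, and decimal formatting.
#'
#' @param x Non-negative scalar below 2^53, or a numeric limb vector (base
#'   1e6, little-endian) when `limbs = TRUE`.
#' @param limbs Interpret `x` as a limb vector.
#' @return An object of class `bigcount`.
#' @seealso [sequence_space()], [big_pow()]
#' @export
bigcount <- function(x, limbs = FALSE) {
  if (limbs) {
    d <- as.numeric(x)
  } else {
    stopifnot(length(x) == 1, is.numeric(x), !is.na(x), x >= 0, x < 2^53,
              x == floor(x))
    d <- numeric(0)
    repeat {
      d <- c(d, x %% BIG_BASE)
      x <- x %/% BIG_BASE
      if (x == 0) break
    }
  }
  structure(list(limbs = big_trim(d)), class = "bigcount")
}

big_trim <- function(d) {
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  d
}

#' @rdname bigcount
#' @param a,b `bigcount` objects.
#' @export
big_mul <- function(a, b) {
  stopifnot(inherits(a, "bigcount"), inherits(b, "bigcount"))
  x <- a$limbs; y <- b$limbs
  out <- numeric(length(x) + length(y))
  for (i in seq_along(x)) {
    if (x[i] == 0) next
    idx <- seq_along(y) + i - 1L
    out[idx] <- out[idx] + x[i] * y
    # immediate carry keeps every limb below 2^53
    carry <- 0
    for (j in seq(i, length(out))) {
      v <- out[j] + carry
      out[j] <- v %% BIG_BASE
      carry <- v %/% BIG_BASE
      if (carry == 0 && j >= max(idx)) break
    }
    stopifnot(carry == 0)
  }
  bigcount(out, limbs = TRUE)
}

#' @rdname bigcount
#' @param base,exp Non-negative integer base and exponent.
#' @export
big_pow <- function(base, exp) {
  stopifnot(exp >= 0, exp == floor(exp))
  acc <- bigcount(1)
  b <- bigcount(base)
  e <- exp
  while (e > 0) {          # square-and-multiply
    if (e %% 2 == 1) acc <- big_mul(acc, b)
    b <- big_mul(b, b)
    e <- e %/% 2
  }
  acc
}

#' @export
as.double.bigcount <- function(x, ...) {
  sum(x$limbs * BIG_BASE^(seq_along(x$limbs) - 1))
}

#' @export
format.bigcount <- function(x, ...) {
  d <- rev(x$limbs)
  s <- paste0(c(format(d[1], scientific = FALSE),
                sprintf("%06d", d[-1])), collapse = "")
  s
}

#' @export
print.bigcount <- function(x, ...) {
  v <- as.numeric(x)
  cat(format(x), sprintf(" (%.4g)\n", v))
  invisible(x)
}

#' @export
`==.bigcount` <- function(e1, e2) {
  if (!inherits(e1, "bigcount")) e1 <- bigcount(e1)
  if (!inherits(e2, "bigcount")) e2 <- bigcount(e2)
  identical(big_trim(e1$limbs), big_trim(e2$limbs))
}
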