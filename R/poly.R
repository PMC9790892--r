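# Minimal multivariate polynomial normaliser.
#
# Polynomials are named numeric vectors: names are canonical monomial keys
# ("1", "x", "x^2*y", with variables sorted alphabetically), values are
# coefficients. Enough machinery to expand products of sums with integer
# powers, which is all the rational-identity proofs of the error-system
# reduction need (numerators after cross-multiplication are polynomial).

mono_key <- function(pows) {
  pows <- pows[pows != 0]
  if (length(pows) == 0L) return("1")
  pows <- pows[order(names(pows))]
  paste(ifelse(pows == 1L, names(pows),
               paste0(names(pows), "^", pows)), collapse = "*")
}

mono_parse <- function(key) {
  if (key == "1") return(integer(0))
  parts <- strsplit(key, "*", fixed = TRUE)[[1]]
  pows <- integer(length(parts))
  vars <- character(length(parts))
  for (i in seq_along(parts)) {
    bits <- strsplit(parts[i], "^", fixed = TRUE)[[1]]
    vars[i] <- bits[1]
    pows[i] <- if (length(bits) == 2L) as.integer(bits[2]) else 1L
  }
  names(pows) <- vars
  pows
}

poly_const <- function(x) stats::setNames(as.numeric(x), "1")

poly_var <- function(v) stats::setNames(1, v)

poly_trim <- function(p, tol = 1e-12) {
  p <- p[abs(p) > tol]
  if (length(p) == 0L) p <- numeric(0)
  p
}

poly_add <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(keys)), keys)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  poly_trim(out)
}

poly_scale <- function(a, k) poly_trim(a * k)

poly_mul <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) return(numeric(0))
  acc <- list()
  for (ka in names(a)) {
    pa <- mono_parse(ka)
    for (kb in names(b)) {
      pb <- mono_parse(kb)
      keys <- union(names(pa), names(pb))
      pows <- stats::setNames(integer(length(keys)), keys)
      pows[names(pa)] <- pows[names(pa)] + pa
      pows[names(pb)] <- pows[names(pb)] + pb
      key <- mono_key(pows)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + a[[ka]] * b[[kb]]
    }
  }
  poly_trim(unlist(acc))
}

poly_pow <- function(a, n) {
  if (n == 0L) return(poly_const(1))
  out <- a
  for (i in seq_len(n - 1L)) out <- poly_mul(out, a)
  out
}

#' Expand a polynomial expression into canonical monomial form
#'
#' Accepts expressions built from numbers, symbols, `+`, `-`, `*`, `(` and
#' integer `^`. Division and other calls are rejected: rational identities are
#' proved by cross-multiplying first (see [delta_identity()]).
#'
#' @param expr Expression or numeric constant.
#' @return Named numeric vector of monomial coefficients (empty = the zero
#'   polynomial).
#' @export
poly_expand <- function(expr) {
  if (is.numeric(expr)) return(poly_trim(poly_const(expr)))
  if (is.name(expr)) return(poly_var(as.character(expr)))
  if (is.call(expr)) {
    op <- as.character(expr[[1]])
    if (op == "(") return(poly_expand(expr[[2]]))
    if (op == "+" && length(expr) == 3L)
      return(poly_add(poly_expand(expr[[2]]), poly_expand(expr[[3]])))
    if (op == "-" && length(expr) == 3L)
      return(poly_add(poly_expand(expr[[2]]), poly_scale(poly_expand(expr[[3]]), -1)))
    if (op == "+" && length(expr) == 2L) return(poly_expand(expr[[2]]))
    if (op == "-" && length(expr) == 2L) return(poly_scale(poly_expand(expr[[2]]), -1))
    if (op == "*") return(poly_mul(poly_expand(expr[[2]]), poly_expand(expr[[3]])))
    if (op == "^") {
      n <- expr[[3]]
      if (!is.numeric(n) || n != round(n) || n < 0)
        stop("only non-negative integer powers are supported", call. = FALSE)
      return(poly_pow(poly_expand(expr[[2]]), as.integer(n)))
    }
  }
  stop("not a polynomial expression: ", deparse(expr), call. = FALSE)
}

#' Is a polynomial expression identically zero?
#'
#' Exact (coefficient-level) test after full expansion.
#' @param expr Polynomial expression.
#' @return Logical scalar.
#' @export
poly_is_zero <- function(expr) length(poly_expand(expr)) == 0L

#' Are two polynomial expressions identical?
#' @param a,b Polynomial expressions.
#' @return Logical scalar.
#' @export
poly_equal <- function(a, b) poly_is_zero(call("-", a, b))
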