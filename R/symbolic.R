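# Light-weight symbolic layer on base R language objects.
#
# Vector fields and scalars are unevaluated R expressions over the three state
# symbols nu1, nu2, nu3 plus free parameter symbols (Ys, Yo, mu_max0, ...).
# stats::D supplies partial derivatives; the combinators below fold the 0/1
# constants so that structurally trivial results (e.g. a Lie derivative along a
# constant field) come out as the literal they are.

#' State symbols of the CSTR model
#'
#' The three concentrations of the reactor model in fixed order:
#' biomass (`nu1`), substrate (`nu2`), dissolved oxygen (`nu3`).
#' @return Character vector of length 3.
#' @export
state_symbols <- function() c("nu1", "nu2", "nu3")

is_num_const <- function(e) is.numeric(e) && length(e) == 1L

#' @noRd
e_add <- function(a, b) {
  if (is_num_const(a) && is_num_const(b)) return(a + b)
  if (is_num_const(a) && a == 0) return(b)
  if (is_num_const(b) && b == 0) return(a)
  call("+", a, b)
}

#' @noRd
e_sub <- function(a, b) {
  if (is_num_const(a) && is_num_const(b)) return(a - b)
  if (is_num_const(b) && b == 0) return(a)
  if (is_num_const(a) && a == 0) return(e_neg(b))
  call("-", a, b)
}

#' @noRd
e_neg <- function(a) {
  if (is_num_const(a)) return(-a)
  call("-", a)
}

#' @noRd
e_mul <- function(a, b) {
  if (is_num_const(a) && is_num_const(b)) return(a * b)
  if (is_num_const(a)) {
    if (a == 0) return(0)
    if (a == 1) return(b)
    if (a == -1) return(e_neg(b))
  }
  if (is_num_const(b)) {
    if (b == 0) return(0)
    if (b == 1) return(a)
    if (b == -1) return(e_neg(a))
  }
  call("*", a, b)
}

#' @noRd
e_div <- function(a, b) {
  if (is_num_const(a) && a == 0) return(0)
  if (is_num_const(b) && b == 1) return(a)
  if (is_num_const(a) && is_num_const(b)) return(a / b)
  call("/", a, b)
}

#' Sum a list of expressions
#' @noRd
e_sum <- function(terms) Reduce(e_add, terms, 0)

#' Substitute symbols in an expression
#'
#' @param expr A language object (or numeric constant).
#' @param env Named list mapping symbol names to replacement expressions or
#'   numeric constants.
#' @return The expression with every occurrence replaced.
#' @export
expr_substitute <- function(expr, env) {
  env <- lapply(env, function(v) if (is.numeric(v)) v else v)
  do.call(substitute, list(expr, env))
}

#' Partial derivative of an expression
#'
#' Thin wrapper over [stats::D] that accepts numeric constants.
#' @param expr Expression or numeric constant.
#' @param var Name of the differentiation variable.
#' @return Expression (or numeric 0).
#' @export
expr_deriv <- function(expr, var) {
  if (is_num_const(expr)) return(0)
  d <- stats::D(expr, var)
  if (is_num_const(d)) d else d
}

#' Gradient of a scalar expression with respect to the state
#'
#' @param expr Scalar expression over the state symbols.
#' @param states Character vector of state symbol names.
#' @return List of partial-derivative expressions, one per state.
#' @export
expr_gradient <- function(expr, states = state_symbols()) {
  lapply(states, function(s) expr_deriv(expr, s))
}

#' Lie derivative of a scalar along a vector field
#'
#' Computes \eqn{L_f h = \nabla h \cdot f} symbolically: the directional
#' derivative of the scalar `scalar` along the field `field`, the basic
#' operation of the observability map and of the matching condition.
#'
#' @param field List of expressions (one component per state symbol).
#' @param scalar Scalar expression over the same state symbols.
#' @param states Character vector of state symbol names.
#' @return An expression (simplified in the trivial-constant cases).
#' @examples
#' lie_derivative(list(1, quote(-(1/Ys)), quote(-(1/Yo))), quote(nu1))
#' @export
lie_derivative <- function(field, scalar, states = state_symbols()) {
  if (length(field) != length(states)) {
    stop("`field` must have one component per state symbol", call. = FALSE)
  }
  terms <- mapply(function(f, s) e_mul(expr_deriv(scalar, s), f),
                  field, states, SIMPLIFY = FALSE)
  e_sum(terms)
}

#' Evaluate an expression in a named environment
#'
#' @param expr Expression or numeric constant.
#' @param env Named list of numeric values (states, parameters, inputs).
#' @return Numeric value.
#' @export
expr_eval <- function(expr, env) {
  if (is_num_const(expr)) return(expr)
  eval(expr, envir = env, enclos = baseenv())
}

#' Simplify an expression by constant folding
#'
#' Recursively removes arithmetic identities (`x + 0`, `x * 1`, `x * 0`,
#' `x - 0`, double negation) and folds numeric sub-expressions. Used to keep
#' substituted error-system expressions readable; it is a tidying pass, not a
#' full canonicaliser.
#'
#' @param expr Expression or numeric constant.
#' @return Simplified expression.
#' @export
expr_simplify <- function(expr) {
  if (is_num_const(expr) || is.name(expr)) return(expr)
  if (!is.call(expr)) return(expr)
  op <- as.character(expr[[1]])
  if (op == "(") {
    inner <- expr_simplify(expr[[2]])
    return(if (is_num_const(inner) || is.name(inner)) inner else call("(", inner))
  }
  args <- lapply(as.list(expr)[-1], expr_simplify)
  if (op == "+" && length(args) == 2L) return(e_add(args[[1]], args[[2]]))
  if (op == "-" && length(args) == 2L) return(e_sub(args[[1]], args[[2]]))
  if (op == "-" && length(args) == 1L) return(e_neg(args[[1]]))
  if (op == "+" && length(args) == 1L) return(args[[1]])
  if (op == "*") return(e_mul(args[[1]], args[[2]]))
  if (op == "/") return(e_div(args[[1]], args[[2]]))
  if (op == "^" && is_num_const(args[[1]]) && is_num_const(args[[2]]))
    return(args[[1]]^args[[2]])
  as.call(c(expr[[1]], args))
}

#' Run code with a temporary RNG seed, restoring the previous state
#' @noRd
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Test whether an expression is (numerically) the zero expression
#'
#' Structural zero constants are recognised directly; otherwise the expression
#' is evaluated at `n` random points of the supplied variable box and declared
#' zero when every sample is below `tol`. Sampling uses a private RNG stream,
#' leaving the caller's RNG state untouched.
#'
#' @param expr Expression.
#' @param vars Named list of `c(lower, upper)` ranges for each free symbol.
#' @param n Number of sample points.
#' @param tol Absolute tolerance.
#' @param seed Seed of the private sampling stream.
#' @return Logical scalar.
#' @export
expr_is_zero <- function(expr, vars, n = 50, tol = 1e-10, seed = 421L) {
  if (is_num_const(expr)) return(expr == 0)
  free <- intersect(all.vars(expr), names(vars))
  if (length(free) == 0L) {
    return(abs(expr_eval(expr, list())) < tol)
  }
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      env <- lapply(vars, function(r) stats::runif(1, r[1], r[2]))
      if (abs(expr_eval(expr, env)) >= tol) return(FALSE)
    }
    TRUE
  })
}

#' Which of the given symbols does an expression genuinely depend on?
#'
#' A symbol counts as a genuine dependency when it occurs in the expression and
#' the partial derivative with respect to it is not the zero expression over
#' the sampling box.
#'
#' @param expr Expression.
#' @param syms Candidate symbol names.
#' @param vars Named list of sampling ranges covering all free symbols.
#' @return Character vector, subset of `syms`.
#' @export
expr_dependencies <- function(expr, syms, vars) {
  if (is_num_const(expr)) return(character(0))
  present <- intersect(all.vars(expr), syms)
  keep <- vapply(present, function(s) {
    !expr_is_zero(expr_deriv(expr, s), vars)
  }, logical(1))
  present[keep]
}
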