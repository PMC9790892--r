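# The cognitive CSTR model and its uncertainty-decomposed affine form.
#
# States: nu1 = biomass X, nu2 = substrate S, nu3 = dissolved oxygen O (g/L).
# Known inputs: u1 = dilution rate D(t), u2 = oxygen transfer kLa(t) (1/h).
# The uncertain reaction kinetics r(t) = mu_SO(t) * nu1 is replaced by the
# substitute kinetics mu_hat * nu1; the mismatch is eliminated into the scalar
# unknown input Delta = (mu_SO - mu_hat) * nu1 acting along the constant
# direction rho = (1, -1/Ys, -1/Yo).

#' CSTR parameter set
#'
#' Yield, inflow, saturation, mortality and maintenance constants of the
#' aerobic CSTR balance model. Defaults are plausible magnitudes for an
#' aerobic wastewater reactor; the analysis results are structural and do not
#' hinge on them.
#'
#' @param Ys Substrate yield coefficient (dimensionless).
#' @param Yo Oxygen yield coefficient (dimensionless).
#' @param Sin Inflow substrate concentration, g/L.
#' @param Oin Inflow dissolved-oxygen concentration, g/L.
#' @param Os Dissolved-oxygen saturation constant, g/L.
#' @param beta_m Biomass mortality rate, 1/h.
#' @param ms Substrate maintenance coefficient, 1/h.
#' @param mo Oxygen maintenance coefficient, 1/h.
#' @return Object of class `cstr_parameters` (a validated named list).
#' @export
cstr_parameters <- function(Ys = 0.65, Yo = 0.2, Sin = 5, Oin = 0.5, Os = 10,
                            beta_m = 0.05, ms = 0.05, mo = 0.02) {
  p <- list(Ys = Ys, Yo = Yo, Sin = Sin, Oin = Oin, Os = Os,
            beta_m = beta_m, ms = ms, mo = mo)
  bad <- vapply(p, function(x)
    !is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0, logical(1))
  if (any(bad))
    stop("all CSTR parameters must be single positive numbers: ",
         paste(names(p)[bad], collapse = ", "), call. = FALSE)
  structure(p, class = "cstr_parameters")
}

#' Bounds of the invariant state set
#'
#' The box of positive concentration bounds within which trajectories are
#' assumed to remain (the invariant set of the model).
#'
#' @param lower,upper Numeric vectors of 3 (biomass, substrate, oxygen), g/L.
#' @return Object of class `omega_bounds`.
#' @export
omega_bounds <- function(lower = c(0.05, 0.2, 0.05), upper = c(3, 6, 9)) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L)
    stop("bounds must have length 3", call. = FALSE)
  if (any(!is.finite(c(lower, upper))) || any(lower <= 0) ||
      any(lower >= upper))
    stop("bounds must satisfy 0 < lower < upper componentwise", call. = FALSE)
  structure(list(lower = stats::setNames(lower, state_symbols()),
                 upper = stats::setNames(upper, state_symbols())),
            class = "omega_bounds")
}

#' Is a state inside the invariant set?
#' @param state Numeric vector of 3 concentrations.
#' @param omega An `omega_bounds` object.
#' @return Logical scalar.
#' @export
in_omega <- function(state, omega = omega_bounds()) {
  state <- as.numeric(state)
  all(is.finite(state)) && all(state >= omega$lower) && all(state <= omega$upper)
}

#' Build the affine analysis model for one case
#'
#' Constructs the symbolic components of the uncertainty-decomposed affine
#' model: the exactly known drift (substitute kinetics plus mortality and
#' maintenance), the two known-input fields (dilution and aeration), the
#' constant uncertainty direction `rho = (1, -1/Ys, -1/Yo)`, and the measured
#' output `h = nu_j`.
#'
#' @param params A `cstr_parameters` object.
#' @param sub A `substitute_kinetics` object (the exactly known kinetics).
#' @param output_index Which state is measured: 1 (biomass), 2 (substrate) or
#'   3 (dissolved oxygen).
#' @return Object of class `affine_model` with fields `drift`, `field_u1`,
#'   `field_u2`, `field_rho` (lists of expressions), `h`, `output_index`,
#'   `params`, `sub`.
#' @export
build_affine_model <- function(params = cstr_parameters(),
                               sub = substitute_kinetics(0.4, 1, 0.2, "SO"),
                               output_index = 3L) {
  stopifnot(inherits(params, "cstr_parameters"),
            inherits(sub, "substitute_kinetics"))
  if (!output_index %in% 1:3)
    stop("`output_index` must be 1, 2 or 3", call. = FALSE)
  mu <- mu_hat_expr(sub$form)
  drift <- list(
    bquote(.(mu) * nu1 - beta_m * nu1),
    bquote(-(1 / Ys) * (.(mu) * nu1) - ms * nu1),
    bquote(-(1 / Yo) * (.(mu) * nu1) - mo * nu1)
  )
  field_u1 <- list(quote(-nu1), quote(Sin - nu2), quote(Oin - nu3))
  field_u2 <- list(0, 0, quote(Os - nu3))
  field_rho <- list(1, quote(-(1 / Ys)), quote(-(1 / Yo)))
  structure(list(
    drift = drift, field_u1 = field_u1, field_u2 = field_u2,
    field_rho = field_rho,
    h = as.name(paste0("nu", output_index)),
    output_index = as.integer(output_index),
    params = params, sub = sub
  ), class = "affine_model")
}

#' @export
print.affine_model <- function(x, ...) {
  cat("Affine CSTR analysis model\n")
  cat("  measured output: nu", x$output_index,
      c(" (biomass)", " (substrate)", " (dissolved oxygen)")[x$output_index],
      "\n", sep = "")
  cat("  substitute kinetics form:", x$sub$form, "\n")
  cat("  drift:\n")
  for (d in x$drift) cat("    ", deparse(d), "\n")
  invisible(x)
}

#' Numeric evaluation environment for a model
#'
#' Collects state values, model parameters and substitute-kinetics constants
#' into one named list suitable for [expr_eval()].
#'
#' @param model An `affine_model`.
#' @param state Numeric vector of 3 concentrations (optional).
#' @param extra Additional named values (inputs, error symbols, ...).
#' @return Named list.
#' @export
model_env <- function(model, state = NULL, extra = list()) {
  env <- c(unclass(model$params),
           list(mu_max0 = model$sub$mu_max0))
  if (!is.null(model$sub$Ks0)) env$Ks0 <- model$sub$Ks0
  if (!is.null(model$sub$Ko0)) env$Ko0 <- model$sub$Ko0
  if (!is.null(state)) {
    state <- as.numeric(state)
    env[state_symbols()] <- state
  }
  utils::modifyList(env, extra)
}

#' Evaluate a symbolic vector field numerically
#'
#' @param field List of expressions.
#' @param env Named list of values for every free symbol.
#' @return Numeric vector.
#' @export
eval_field <- function(field, env) {
  vapply(field, expr_eval, numeric(1), env = env)
}

#' Right-hand side of the affine analysis model
#'
#' `drift + field_u1 * u1 + field_u2 * u2 + rho * delta`, evaluated at a
#' numeric state.
#'
#' @param model An `affine_model`.
#' @param state Numeric state vector.
#' @param u1,u2 Known input values (dilution, oxygen transfer), 1/h.
#' @param delta Unknown-input value (0 for the nominal substitute model).
#' @return Numeric vector of 3 time derivatives, g/L/h.
#' @export
affine_rhs <- function(model, state, u1, u2, delta = 0) {
  env <- model_env(model, state)
  eval_field(model$drift, env) +
    u1 * eval_field(model$field_u1, env) +
    u2 * eval_field(model$field_u2, env) +
    delta * eval_field(model$field_rho, env)
}

#' Right-hand side of the cognitive (true) CSTR model
#'
#' The mass-balance model with the time-varying true kinetics
#' `r(t) = mu_SO(t) * nu1`: growth, dilution, aeration, mortality and
#' maintenance.
#'
#' @param state Numeric state vector `c(X, S, O)`, g/L.
#' @param params A `cstr_parameters` object.
#' @param true_kin A `true_kinetics` object (product form is the reference
#'   truth of the analysis).
#' @param inputs An `input_signals` object (see [input_signals()]).
#' @param t Time, h.
#' @return Numeric vector of 3 derivatives.
#' @export
true_rhs <- function(state, params, true_kin, inputs, t) {
  stopifnot(inherits(params, "cstr_parameters"))
  state <- as.numeric(state)
  mu <- monod_rate(pmax(state, 0), true_kin, t)
  r <- mu * state[1]
  D <- signal_value(inputs$u1, t)
  kla <- signal_value(inputs$u2, t)
  c(r - params$beta_m * state[1] - state[1] * D,
    -r / params$Ys - params$ms * state[1] + (params$Sin - state[2]) * D,
    -r / params$Yo - params$mo * state[1] + (params$Oin - state[3]) * D +
      (params$Os - state[3]) * kla)
}

#' The eliminated-uncertainty unknown input
#'
#' `Delta(nu, t) = (mu_SO_true(t) - mu_hat(nu)) * nu1`: the kinetics mismatch
#' scaled by biomass, the scalar unknown input of the affine model. Zero
#' whenever biomass is zero.
#'
#' @param state Numeric state vector.
#' @param true_kin A `true_kinetics` object.
#' @param sub A `substitute_kinetics` object.
#' @param t Time, h.
#' @return Scalar, units of a rate term (1/h * g/L).
#' @export
delta_unknown_input <- function(state, true_kin, sub, t) {
  state <- as.numeric(state)
  (monod_rate(state, true_kin, t) - monod_rate(state, sub, t)) * state[1]
}
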