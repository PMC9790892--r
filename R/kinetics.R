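# Monod growth kinetics: time-varying "true" kinetics with bounded parameters,
# and the time-invariant substitute kinetics obtained by mean parameterisation.

KIN_FORMS <- c("S", "O", "SO")

form_arg_states <- function(form) {
  switch(form, S = 2L, O = 3L, SO = c(2L, 3L),
         stop("unknown kinetics form: ", form, call. = FALSE))
}

#' Time-invariant substitute Monod kinetics
#'
#' The exactly known growth-rate function used inside the analysis model:
#' a Monod factor in substrate (`form = "S"`), in dissolved oxygen
#' (`form = "O"`), or their product (`form = "SO"`), with constant parameters.
#'
#' @param mu_max0 Maximum specific growth rate, 1/h.
#' @param Ks0 Substrate half-saturation constant, g/L (forms "S" and "SO").
#' @param Ko0 Oxygen half-saturation constant, g/L (forms "O" and "SO").
#' @param form One of `"S"`, `"O"`, `"SO"`.
#' @return Object of class `substitute_kinetics`.
#' @export
substitute_kinetics <- function(mu_max0, Ks0 = NULL, Ko0 = NULL, form = "SO") {
  form <- match.arg(form, KIN_FORMS)
  need_s <- form %in% c("S", "SO")
  need_o <- form %in% c("O", "SO")
  chk <- function(x, nm) {
    if (is.null(x)) stop("`", nm, "` is required for form ", form, call. = FALSE)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("`", nm, "` must be a single positive number", call. = FALSE)
    x
  }
  out <- list(
    mu_max0 = chk(mu_max0, "mu_max0"),
    Ks0 = if (need_s) chk(Ks0, "Ks0") else Ks0,
    Ko0 = if (need_o) chk(Ko0, "Ko0") else Ko0,
    form = form
  )
  structure(out, class = "substitute_kinetics")
}

#' @export
print.substitute_kinetics <- function(x, ...) {
  cat("Substitute Monod kinetics, form", x$form, "\n")
  cat("  mu_max0 =", x$mu_max0, "1/h")
  if (!is.null(x$Ks0)) cat(", Ks0 =", x$Ks0, "g/L")
  if (!is.null(x$Ko0)) cat(", Ko0 =", x$Ko0, "g/L")
  cat("\n")
  invisible(x)
}

check_interval <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop("`", nm, "` must be a numeric interval c(min, max)", call. = FALSE)
  if (x[1] <= 0 || x[1] > x[2])
    stop("`", nm, "` must satisfy 0 < min <= max", call. = FALSE)
  x
}

#' Time-varying true Monod kinetics
#'
#' The uncertain "real" kinetics of the reactor: Monod parameters are smooth
#' bounded positive signals, realised as the interval midpoint plus a sinusoid
#' whose amplitude is `amp_frac` of the half-width (so the bounds are respected
#' strictly).
#'
#' @param mu_max,Ks,Ko Intervals `c(min, max)` for the time-varying
#'   parameters (1/h, g/L, g/L).
#' @param form One of `"S"`, `"O"`, `"SO"`; the product form is the one the
#'   analysis treats as the real kinetics.
#' @param period Common oscillation period, h.
#' @param phase Numeric vector of 3 phases (radians) for mu_max, Ks, Ko.
#' @param amp_frac Fraction of the half-width used as oscillation amplitude,
#'   in `[0, 1)`.
#' @return Object of class `true_kinetics`.
#' @export
true_kinetics <- function(mu_max = c(0.3, 0.5), Ks = c(0.5, 1.5),
                          Ko = c(0.1, 0.3), form = "SO", period = 24,
                          phase = c(0, pi / 3, 2 * pi / 3), amp_frac = 0.8) {
  form <- match.arg(form, KIN_FORMS)
  if (amp_frac < 0 || amp_frac >= 1)
    stop("`amp_frac` must be in [0, 1)", call. = FALSE)
  structure(list(
    mu_max = check_interval(mu_max, "mu_max"),
    Ks = check_interval(Ks, "Ks"),
    Ko = check_interval(Ko, "Ko"),
    form = form, period = period, phase = rep_len(phase, 3L),
    amp_frac = amp_frac
  ), class = "true_kinetics")
}

#' Evaluate the time-varying kinetics parameters
#'
#' @param kin A `true_kinetics` object.
#' @param t Time(s), h.
#' @return List with numeric vectors `mu_max`, `Ks`, `Ko` at `t`.
#' @export
kinetics_at <- function(kin, t) {
  stopifnot(inherits(kin, "true_kinetics"))
  wave <- function(iv, ph) {
    mid <- mean(iv); half <- diff(iv) / 2
    mid + kin$amp_frac * half * sin(2 * pi * t / kin$period + ph)
  }
  list(mu_max = wave(kin$mu_max, kin$phase[1]),
       Ks = wave(kin$Ks, kin$phase[2]),
       Ko = wave(kin$Ko, kin$phase[3]))
}

#' Mean parameterisation of the substitute kinetics
#'
#' Builds the time-invariant substitute kinetics from the bounds of the true
#' kinetics: each constant is the arithmetic midpoint of the corresponding
#' interval; the functional form is carried through.
#'
#' @param kin A `true_kinetics` object, or a list with interval fields
#'   `mu_max`, `Ks`, `Ko` and a `form`.
#' @param form Optional form override for the substitute function (the nine
#'   analysis cases pair the product-form truth with all three substitutes).
#' @return A `substitute_kinetics` object.
#' @export
mean_parameterize <- function(kin, form = NULL) {
  if (!inherits(kin, "true_kinetics")) {
    kin <- true_kinetics(mu_max = kin$mu_max, Ks = kin$Ks, Ko = kin$Ko,
                         form = if (is.null(kin$form)) "SO" else kin$form)
  }
  form <- if (is.null(form)) kin$form else match.arg(form, KIN_FORMS)
  substitute_kinetics(mu_max0 = mean(kin$mu_max),
                      Ks0 = mean(kin$Ks), Ko0 = mean(kin$Ko), form = form)
}

#' Specific growth rate
#'
#' Evaluates the Monod growth-rate function \eqn{\mu} for a state, for either
#' time-invariant substitute kinetics or time-varying true kinetics.
#'
#' @param state Numeric vector `c(nu1, nu2, nu3)` of concentrations, g/L.
#' @param kin A `substitute_kinetics` or `true_kinetics` object.
#' @param t Time, h (used only for `true_kinetics`).
#' @return Specific growth rate, 1/h; in `[0, mu_max)`.
#' @export
monod_rate <- function(state, kin, t = 0) {
  state <- as.numeric(state)
  if (length(state) != 3L || any(!is.finite(state)) || any(state < 0))
    stop("`state` must be three finite non-negative concentrations", call. = FALSE)
  if (inherits(kin, "true_kinetics")) {
    p <- kinetics_at(kin, t)
    mu_max <- p$mu_max; Ks <- p$Ks; Ko <- p$Ko; form <- kin$form
  } else if (inherits(kin, "substitute_kinetics")) {
    mu_max <- kin$mu_max0; Ks <- kin$Ks0; Ko <- kin$Ko0; form <- kin$form
  } else stop("`kin` must be substitute_kinetics or true_kinetics", call. = FALSE)
  if (mu_max <= 0 || (form != "O" && Ks <= 0) || (form != "S" && Ko <= 0))
    stop("kinetics parameters must be positive", call. = FALSE)
  s_fac <- state[2] / (Ks + state[2])
  o_fac <- state[3] / (Ko + state[3])
  switch(form,
         S = mu_max * s_fac,
         O = mu_max * o_fac,
         SO = mu_max * s_fac * o_fac)
}

#' Symbolic substitute growth-rate expression
#'
#' Returns the substitute Monod function as an unevaluated expression over the
#' state symbols and the parameter symbols `mu_max0`, `Ks0`, `Ko0`.
#'
#' @param form One of `"S"`, `"O"`, `"SO"`.
#' @param s Symbol (or expression) standing for substrate; defaults to `nu2`.
#' @param o Symbol (or expression) standing for oxygen; defaults to `nu3`.
#' @return A language object.
#' @export
mu_hat_expr <- function(form, s = quote(nu2), o = quote(nu3)) {
  form <- match.arg(form, KIN_FORMS)
  s_fac <- bquote(.(s) / (Ks0 + .(s)))
  o_fac <- bquote(.(o) / (Ko0 + .(o)))
  switch(form,
         S = bquote(mu_max0 * .(s_fac)),
         O = bquote(mu_max0 * .(o_fac)),
         SO = bquote(mu_max0 * .(s_fac) * .(o_fac)))
}
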