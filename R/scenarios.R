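# Seeded synthetic scenarios: parameter draws, bounded positive input signals,
# time-varying true kinetics and initial conditions inside the invariant box.

#' Bounded positive input signal
#'
#' Represents one known input (dilution rate or oxygen mass-transfer
#' coefficient) as a fully parameterised time function: constant, sinusoid
#' around a base level, or a piecewise-constant profile. All realisations
#' satisfy `0 < signal(t) <= bound`.
#'
#' @param kind `"constant"`, `"sinusoid"` or `"piecewise"`.
#' @param bound Upper bound of the signal, 1/h.
#' @param base Base level (defaults to 60% of the bound).
#' @param amp Oscillation amplitude (sinusoid only).
#' @param period Oscillation period, h.
#' @param phase Phase, radians.
#' @param levels,breaks Piecewise levels and interior breakpoints, h.
#' @return Object of class `input_signal`.
#' @export
input_signal <- function(kind = c("constant", "sinusoid", "piecewise"),
                         bound, base = 0.6 * bound, amp = 0.25 * base,
                         period = 12, phase = 0, levels = NULL, breaks = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(bound) || bound <= 0)
    stop("`bound` must be positive", call. = FALSE)
  sig <- list(kind = kind, bound = bound, base = base, amp = amp,
              period = period, phase = phase, levels = levels, breaks = breaks)
  if (kind == "constant" && (base <= 0 || base > bound))
    stop("constant level must lie in (0, bound]", call. = FALSE)
  if (kind == "sinusoid" && (base - abs(amp) <= 0 || base + abs(amp) > bound))
    stop("sinusoid must stay in (0, bound]", call. = FALSE)
  if (kind == "piecewise") {
    if (is.null(levels) || any(levels <= 0) || any(levels > bound))
      stop("piecewise levels must lie in (0, bound]", call. = FALSE)
    if (length(levels) != length(breaks) + 1L)
      stop("need one more level than breaks", call. = FALSE)
  }
  structure(sig, class = "input_signal")
}

#' Evaluate an input signal
#' @param sig An `input_signal`.
#' @param t Time(s), h.
#' @return Numeric vector of signal values.
#' @export
signal_value <- function(sig, t) {
  stopifnot(inherits(sig, "input_signal"))
  switch(sig$kind,
         constant = rep_len(sig$base, length(t)),
         sinusoid = sig$base + sig$amp * sin(2 * pi * t / sig$period + sig$phase),
         piecewise = sig$levels[findInterval(t, sig$breaks) + 1L])
}

#' Generate one bounded positive input signal
#'
#' @param seed Integer seed (private stream; caller's RNG untouched).
#' @param bound Upper bound, must be positive.
#' @param kind Signal shape, see [input_signal()].
#' @param period Oscillation period for sinusoids, h.
#' @return An `input_signal`.
#' @export
generate_input_signal <- function(seed, bound,
                                  kind = c("sinusoid", "constant", "piecewise"),
                                  period = 12) {
  kind <- match.arg(kind)
  if (!is.numeric(bound) || bound <= 0)
    stop("`bound` must be positive", call. = FALSE)
  with_local_seed(seed, {
    base <- stats::runif(1, 0.45, 0.75) * bound
    switch(kind,
      constant = input_signal("constant", bound, base = base),
      sinusoid = input_signal("sinusoid", bound, base = base,
                              amp = stats::runif(1, 0.1, 0.3) * base,
                              period = period,
                              phase = stats::runif(1, 0, 2 * pi)),
      piecewise = {
        k <- sample(2:4, 1)
        input_signal("piecewise", bound,
                     levels = stats::runif(k + 1, 0.3, 1) * bound,
                     breaks = sort(stats::runif(k, 5, 45)))
      })
  })
}

#' Generate a complete seeded simulation scenario
#'
#' Draws a fully specified scenario: CSTR parameters uniform within ±20% of
#' the canonical defaults, true-kinetics bounds at their canonical values,
#' bounded positive input signals, and two distinct initial conditions inside
#' the invariant box (minimum separation 1e-3 g/L per component, so that
#' convergence checks are non-trivial). Regeneration with the same seed is
#' bit-for-bit identical.
#'
#' @param seed Integer seed.
#' @param washout If `TRUE`, the original initial biomass is set to zero (the
#'   wash-out regime, from which biomass cannot recover).
#' @param equal_ic If `TRUE`, the copy initial condition equals the original.
#' @param horizon Numeric `c(t0, tf)`, h.
#' @param omega An `omega_bounds` object.
#' @param u1_bound,u2_bound Upper bounds on dilution rate and kLa, 1/h.
#' @param input_kind Shape of the generated input signals.
#' @return Object of class `scenario_bundle`.
#' @export
generate_scenario <- function(seed, washout = FALSE, equal_ic = FALSE,
                              horizon = c(0, 50), omega = omega_bounds(),
                              u1_bound = 0.2, u2_bound = 6,
                              input_kind = "sinusoid") {
  if (diff(horizon) <= 0) stop("horizon length must be positive", call. = FALSE)
  with_local_seed(seed, {
    jig <- function(x) x * stats::runif(1, 0.8, 1.2)
    d <- cstr_parameters()
    params <- cstr_parameters(Ys = jig(d$Ys), Yo = jig(d$Yo), Sin = jig(d$Sin),
                              Oin = jig(d$Oin), Os = d$Os,
                              beta_m = jig(d$beta_m), ms = jig(d$ms),
                              mo = jig(d$mo))
    true_kin <- true_kinetics(form = "SO",
                              phase = stats::runif(3, 0, 2 * pi))
    u1 <- generate_input_signal(sample.int(2^30, 1), u1_bound, input_kind)
    u2 <- generate_input_signal(sample.int(2^30, 1), u2_bound, input_kind)
    draw_ic <- function() {
      stats::runif(3, omega$lower, omega$upper)
    }
    ic_original <- draw_ic()
    if (washout) ic_original[1] <- 0
    if (equal_ic) {
      ic_copy <- ic_original
    } else {
      repeat {
        ic_copy <- draw_ic()
        if (all(abs(ic_copy - ic_original) >= 1e-3)) break
      }
    }
    structure(list(
      params = params, true_kin = true_kin,
      inputs = structure(list(u1 = u1, u2 = u2,
                              u1_bound = u1_bound, u2_bound = u2_bound),
                         class = "input_signals"),
      ic_original = stats::setNames(ic_original, state_symbols()),
      ic_copy = stats::setNames(ic_copy, state_symbols()),
      horizon = horizon, omega = omega, seed = as.integer(seed),
      washout = washout
    ), class = "scenario_bundle")
  })
}

#' Known-input pair container
#'
#' Convenience constructor for the two known inputs when a scenario is built
#' by hand rather than generated.
#'
#' @param u1,u2 `input_signal` objects (dilution rate, oxygen transfer).
#' @return Object of class `input_signals`.
#' @export
input_signals <- function(u1, u2) {
  stopifnot(inherits(u1, "input_signal"), inherits(u2, "input_signal"))
  structure(list(u1 = u1, u2 = u2, u1_bound = u1$bound, u2_bound = u2$bound),
            class = "input_signals")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("CSTR simulation scenario (seed ", x$seed, ")\n", sep = "")
  cat("  horizon:", x$horizon[1], "-", x$horizon[2], "h\n")
  cat("  ic original:", signif(x$ic_original, 4), "g/L\n")
  cat("  ic copy:    ", signif(x$ic_copy, 4), "g/L\n")
  invisible(x)
}

#' Serialise a scenario to a YAML file
#'
#' Writes every defining number of the scenario so a failing case can be
#' replayed exactly.
#'
#' @param scenario A `scenario_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  ser <- list(
    seed = scenario$seed, washout = scenario$washout,
    horizon = scenario$horizon,
    params = unclass(scenario$params),
    true_kin = unclass(scenario$true_kin),
    omega = lapply(unclass(scenario$omega), as.numeric),
    ic_original = as.numeric(scenario$ic_original),
    ic_copy = as.numeric(scenario$ic_copy),
    u1 = Filter(Negate(is.null), unclass(scenario$inputs$u1)),
    u2 = Filter(Negate(is.null), unclass(scenario$inputs$u2))
  )
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' Read a scenario back from YAML
#' @param path File written by [write_scenario()].
#' @return A `scenario_bundle`.
#' @export
read_scenario <- function(path) {
  s <- yaml::read_yaml(path)
  mk_sig <- function(u) {
    input_signal(u$kind, u$bound, base = u$base, amp = u$amp,
                 period = u$period, phase = u$phase,
                 levels = u$levels, breaks = u$breaks)
  }
  structure(list(
    params = do.call(cstr_parameters, s$params),
    true_kin = true_kinetics(mu_max = as.numeric(s$true_kin$mu_max),
                             Ks = as.numeric(s$true_kin$Ks),
                             Ko = as.numeric(s$true_kin$Ko),
                             form = s$true_kin$form,
                             period = s$true_kin$period,
                             phase = as.numeric(s$true_kin$phase),
                             amp_frac = s$true_kin$amp_frac),
    inputs = input_signals(mk_sig(s$u1), mk_sig(s$u2)),
    ic_original = stats::setNames(as.numeric(s$ic_original), state_symbols()),
    ic_copy = stats::setNames(as.numeric(s$ic_copy), state_symbols()),
    horizon = as.numeric(s$horizon),
    omega = omega_bounds(as.numeric(s$omega$lower), as.numeric(s$omega$upper)),
    seed = s$seed, washout = isTRUE(s$washout)
  ), class = "scenario_bundle")
}
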