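rand_env <- function(m, seed) {
  set.seed(seed)
  env <- model_env(m, runif(3, 0.1, 4))
  env[eps_names] <- as.list(runif(3, -0.5, 0.5))
  env$u1 <- runif(1, 0.02, 0.2)
  env$u2 <- runif(1, 0.5, 6)
  env$delta_delta <- runif(1, -0.2, 0.2)
  env
}
eps_names <- c("eps1", "eps2", "eps3")

test_that("the zero point is an equilibrium of every error system", {
  for (case_id in 1:9) {
    m <- model_for_case(case_id)
    for (unc in c(TRUE, FALSE)) {
      err <- build_error_system(m, unc)
      expect_identical(err$dimension, 6L)
      env <- rand_env(m, case_id)
      env[eps_names] <- list(0, 0, 0)
      env$delta_delta <- 0
      expect_equal(vapply(err$rhs, expr_eval, numeric(1), env = env),
                   c(0, 0, 0), tolerance = 1e-14)
    }
  }
})

test_that("the oxygen error equation carries the combined dilution+aeration decay", {
  # substrate-only kinetics: the only eps3 dependence of the third equation
  # is the -(u1 + u2) eps3 term
  m <- model_for_case(4)
  err <- build_error_system(m, TRUE)
  env <- rand_env(m, 4)
  d <- expr_deriv(err$rhs[[3]], "eps3")
  expect_equal(expr_eval(d, env), -(env$u1 + env$u2), tolerance = 1e-12)
  # oxygen-only kinetics: the substrate error decays at the dilution rate
  m1 <- model_for_case(1)
  err1 <- build_error_system(m1, TRUE)
  env1 <- rand_env(m1, 5)
  d2 <- expr_deriv(err1$rhs[[2]], "eps2")
  expect_equal(expr_eval(d2, env1), -env1$u1, tolerance = 1e-12)
})

test_that("case 1 reduction reproduces the printed algebraic and biomass parts", {
  m <- model_for_case(1)  # oxygen measured, oxygen-only kinetics
  red <- reduce_for_output(build_error_system(m, TRUE), m)
  p <- m$params
  for (seed in 1:20) {
    env <- rand_env(m, seed)
    env$eps3 <- 0
    mu_o <- m$sub$mu_max0 * env$nu3 / (m$sub$Ko0 + env$nu3)
    # delta_delta = -eps1 (mu_O + Yo mo)
    expect_equal(expr_eval(red$algebraic, env),
                 -env$eps1 * (mu_o + p$Yo * p$mo), tolerance = 1e-12)
    # eps1' = -eps1 (beta_m + u1 + Yo mo)
    env$delta_delta <- expr_eval(red$algebraic, env)
    expect_equal(expr_eval(red$differential$eps1, env),
                 -env$eps1 * (p$beta_m + env$u1 + p$Yo * p$mo),
                 tolerance = 1e-12)
  }
  expect_true(red$mu_equalized)
  expect_true(red$closed_form)
})

test_that("case 5 reduction gives pure input-driven decay and a Monod-difference input", {
  m <- model_for_case(5)  # biomass measured, substrate-only kinetics
  red <- reduce_for_output(build_error_system(m, TRUE), m)
  for (seed in 1:20) {
    env <- rand_env(m, 100 + seed)
    env$eps1 <- 0
    env$delta_delta <- expr_eval(red$algebraic, env)
    # eps2' = -u1 eps2, eps3' = -(u1+u2) eps3
    expect_equal(expr_eval(red$differential$eps2, env), -env$u1 * env$eps2,
                 tolerance = 1e-12)
    expect_equal(expr_eval(red$differential$eps3, env),
                 -(env$u1 + env$u2) * env$eps3, tolerance = 1e-12)
    # delta_delta = (mu_S' - mu_S) nu1
    mu_s <- function(s) m$sub$mu_max0 * s / (m$sub$Ks0 + s)
    expect_equal(env$delta_delta,
                 (mu_s(env$nu2 - env$eps2) - mu_s(env$nu2)) * env$nu1,
                 tolerance = 1e-12)
  }
  expect_false(red$closed_form)
})

test_that("without uncertainty the measured equation becomes a forcing constraint", {
  m <- model_for_case(1)
  red <- reduce_for_output(build_error_system(m, FALSE), m)
  p <- m$params
  for (seed in 1:10) {
    env <- rand_env(m, 200 + seed)
    env$eps3 <- 0
    mu_o <- m$sub$mu_max0 * env$nu3 / (m$sub$Ko0 + env$nu3)
    # 0 = -(1/Yo) eps1 (mu_O + Yo mo): only eps1 = 0 satisfies it
    expect_equal(expr_eval(red$algebraic, env),
                 -(1 / p$Yo) * env$eps1 * (mu_o + p$Yo * p$mo),
                 tolerance = 1e-12)
  }
  expect_identical(red$constraint_vars, "eps1")
})

test_that("closed-form biomass error matches quadrature for time-varying dilution", {
  m <- model_for_case(1)
  red <- reduce_for_output(build_error_system(m, TRUE), m)
  sc <- generate_scenario(31)
  times <- seq(0, 30, length.out = 61)
  gam <- closed_form_error(red, sc, times, eps1_0 = 0.3)
  # independent quadrature of the input integral
  p <- m$params
  rate0 <- p$beta_m + p$Yo * p$mo
  gam_quad <- vapply(times, function(tt) {
    iu <- stats::integrate(function(s) signal_value(sc$inputs$u1, s), 0, tt,
                           rel.tol = 1e-10)$value
    0.3 * exp(-iu - rate0 * tt)
  }, numeric(1))
  expect_equal(gam, gam_quad, tolerance = 1e-8)
  # zero initial error stays zero
  expect_equal(closed_form_error(red, sc, times, eps1_0 = 0), rep(0, 61))
  # constant dilution: log-slope is exactly the sum of the stated rates
  p2 <- cstr_parameters(beta_m = 0.05, Yo = 0.2, mo = 0.02)
  m2 <- build_affine_model(p2, m$sub, 3L)
  red2 <- reduce_for_output(build_error_system(m2, TRUE), m2)
  sc2 <- sc
  sc2$inputs <- input_signals(input_signal("constant", 0.2, base = 0.1),
                              sc$inputs$u2)
  g <- closed_form_error(red2, sc2, c(0, 10), eps1_0 = 1)
  expect_equal(log(g[2] / g[1]) / 10, -(0.1 + 0.05 + 0.2 * 0.02),
               tolerance = 1e-12)
  # unsupported structure is refused
  m5 <- model_for_case(5)
  red5 <- reduce_for_output(build_error_system(m5, TRUE), m5)
  expect_error(closed_form_error(red5, sc, times), "closed form")
})

test_that("the Monod-difference identity and its constraint are exact", {
  di <- delta_identity()
  expect_true(di$equal)
  expect_true(di$forces_eps2_zero)
  # the uncertainty-free constraint polynomial is the single monomial Ks0*eps2
  expect_identical(names(di$eq_constraint_poly), "Ks0*eps2")
  expect_equal(unname(di$eq_constraint_poly), -1)
  # numeric spot checks of the single-fraction form
  expect_equal(delta_identity(state = c(2, 3, 1), eps2 = 0)$value, 0)
  sub <- substitute_kinetics(0.4, Ks0 = 1, form = "S")
  v <- delta_identity(state = c(2, 3, 1), eps2 = 0.5, sub = sub)$value
  expect_equal(v, 0.4 * (3 / 4 - 2.5 / 3.5) * 2, tolerance = 1e-12)
  expect_error(delta_identity(state = c(1, 2, 1), eps2 = 3, sub = sub),
               "singular")
})

test_that("classification matrices match the frozen case tables", {
  for (case_id in 1:9) {
    m <- model_for_case(case_id)
    red_u <- reduce_for_output(build_error_system(m, TRUE), m)
    red_n <- reduce_for_output(build_error_system(m, FALSE), m)
    for (sub in subcases_of(case_id)) {
      key <- paste0(case_id, ":", sub)
      expect_identical(compact_labels(classify_states(red_u, sub)),
                       expected_with_uncertainty[[key]],
                       label = paste("with uncertainty", key))
      expect_identical(compact_labels(classify_states(red_n, sub)),
                       expected_without_uncertainty[[key]],
                       label = paste("without uncertainty", key))
    }
  }
  # wash-out sub-cases are only defined for the biomass output
  m3 <- model_for_case(3)
  red3 <- reduce_for_output(build_error_system(m3, TRUE), m3)
  expect_error(classify_states(red3, "washout-ic"), "biomass")
})

test_that("removing uncertainty never weakens a generic-regime label", {
  # (the wash-out sub-rows are exempt: with uncertainty their state labels
  # inherit the structural rank verdict, which the vacuous uncertainty-free
  # constraint cannot match)
  rank_of <- c(unobservable = 1, detectable = 2, observable = 3)
  for (case_id in 1:9) {
    m <- model_for_case(case_id)
    lu <- classify_states(reduce_for_output(build_error_system(m, TRUE), m))
    ln <- classify_states(reduce_for_output(build_error_system(m, FALSE), m))
    for (i in 1:3) {
      if (lu$role[i] != "state") next
      expect_gte(rank_of[[ln$label[i]]], rank_of[[lu$label[i]]])
    }
  }
})
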