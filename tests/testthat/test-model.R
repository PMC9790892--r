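test_that("affine model components have the prescribed structure", {
  for (case_id in c(1, 5, 9)) {
    m <- model_for_case(case_id)
    expect_identical(m$field_rho[[1]], 1)
    expect_identical(m$field_rho[[2]], quote(-(1 / Ys)))
    expect_identical(m$field_rho[[3]], quote(-(1 / Yo)))
    # aeration only enters the oxygen balance, proportional to the deficit
    set.seed(3)
    for (k in 1:5) {
      st <- runif(3, 0.1, 5)
      v <- eval_field(m$field_u2, model_env(m, st))
      expect_equal(v, c(0, 0, m$params$Os - st[3]))
    }
    # rho is constant: state Jacobian identically zero
    for (r in m$field_rho) {
      for (s in state_symbols()) expect_identical(expr_deriv(r, s), 0)
    }
  }
  expect_error(build_affine_model(output_index = 4), "output_index")
})

test_that("oxygen-form drift is independent of substrate", {
  m <- model_for_case(1)  # form O
  box <- c(list(nu1 = c(0.1, 3), nu2 = c(0.2, 6), nu3 = c(0.1, 9)),
           lapply(model_env(m), function(v) c(v, v)))
  for (d in m$drift) {
    expect_true(expr_is_zero(expr_deriv(d, "nu2"), box))
  }
  # and so are its Lie derivatives along itself
  obs <- observability_map(m)
  expect_true(expr_is_zero(expr_deriv(obs[[2]], "nu2"), box))
  expect_true(expr_is_zero(expr_deriv(obs[[3]], "nu2"), box))
})

test_that("drift matches a hand-evaluated mass balance at a numeric point", {
  p <- cstr_parameters()
  sub <- substitute_kinetics(0.4, Ks0 = 1, Ko0 = 0.2, form = "SO")
  m <- build_affine_model(p, sub, 3L)
  st <- c(1.5, 2, 0.5)
  mu <- 0.4 * (2 / (1 + 2)) * (0.5 / (0.2 + 0.5))
  expect_equal(
    eval_field(m$drift, model_env(m, st)),
    c(mu * 1.5 - p$beta_m * 1.5,
      -mu * 1.5 / p$Ys - p$ms * 1.5,
      -mu * 1.5 / p$Yo - p$mo * 1.5))
})

test_that("true dynamics decompose exactly into drift + inputs + rho * Delta", {
  sc <- generate_scenario(21)
  set.seed(99)
  for (case_id in c(1, 4, 7, 9)) {
    cr <- enumerate_cases()[case_id, ]
    m <- case_model(cr, sc$params, sc$true_kin)
    for (k in 1:25) {
      st <- runif(3, 0.1, 4)
      t <- runif(1, 0, 50)
      u1 <- signal_value(sc$inputs$u1, t)
      u2 <- signal_value(sc$inputs$u2, t)
      delta <- delta_unknown_input(st, sc$true_kin, m$sub, t)
      expect_equal(true_rhs(st, sc$params, sc$true_kin, sc$inputs, t),
                   affine_rhs(m, st, u1, u2, delta), tolerance = 1e-10)
    }
  }
})

test_that("the unknown input vanishes with biomass and with matching kinetics", {
  sc <- generate_scenario(5)
  sub <- mean_parameterize(sc$true_kin)
  expect_equal(delta_unknown_input(c(0, 2, 1), sc$true_kin, sub, 3), 0)
  # frozen true kinetics identical to the substitute: no mismatch left
  frozen <- true_kinetics(mu_max = rep(sub$mu_max0, 2), Ks = rep(sub$Ks0, 2),
                          Ko = rep(sub$Ko0, 2), form = "SO", amp_frac = 0)
  set.seed(8)
  for (k in 1:10) {
    st <- runif(3, 0, 5)
    expect_equal(delta_unknown_input(st, frozen, sub, runif(1, 0, 50)), 0)
  }
})

test_that("wash-out is invariant and the model preserves positivity", {
  sc <- generate_scenario(13, washout = TRUE)
  expect_equal(true_rhs(sc$ic_original, sc$params, sc$true_kin, sc$inputs, 0)[1], 0)
  # integrate the true model from interior points: states stay non-negative
  for (seed in 1:3) {
    s <- generate_scenario(seed)
    traj <- simulate_model(s, times = seq(0, 50, length.out = 201))
    expect_true(all(as.matrix(traj[, 2:4]) >= 0))
  }
})
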