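test_that("scenario generation is deterministic and seed-sensitive", {
  a <- generate_scenario(42)
  b <- generate_scenario(42)
  expect_identical(a, b)
  c <- generate_scenario(43)
  expect_false(identical(a$ic_original, c$ic_original))
  # and does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(generate_scenario(7)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated scenarios respect the invariant box and input bounds", {
  t <- seq(0, 50, length.out = 1000)
  for (seed in 1:5) {
    sc <- generate_scenario(seed)
    expect_true(in_omega(sc$ic_original, sc$omega))
    expect_true(in_omega(sc$ic_copy, sc$omega))
    expect_true(all(abs(sc$ic_original - sc$ic_copy) >= 1e-3))
    u1 <- signal_value(sc$inputs$u1, t)
    u2 <- signal_value(sc$inputs$u2, t)
    expect_true(all(u1 > 0 & u1 <= sc$inputs$u1_bound))
    expect_true(all(u2 > 0 & u2 <= sc$inputs$u2_bound))
    k <- kinetics_at(sc$true_kin, t)
    expect_true(all(k$mu_max > 0) && all(k$Ks > 0) && all(k$Ko > 0))
  }
})

test_that("wash-out and equal-IC options behave as declared", {
  w <- generate_scenario(9, washout = TRUE)
  expect_equal(unname(w$ic_original[1]), 0)
  expect_true(all(w$ic_original[2:3] > w$omega$lower[2:3]))
  e <- generate_scenario(9, equal_ic = TRUE)
  expect_identical(e$ic_original, e$ic_copy)
  expect_error(generate_scenario(9, horizon = c(10, 10)), "horizon")
})

test_that("input signal kinds stay positive, bounded and seed-distinct", {
  t <- seq(0, 50, length.out = 500)
  for (kind in c("constant", "sinusoid", "piecewise")) {
    sig <- generate_input_signal(4, 0.2, kind)
    v <- signal_value(sig, t)
    expect_true(all(v > 0 & v <= 0.2))
    sig2 <- generate_input_signal(5, 0.2, kind)
    expect_false(identical(signal_value(sig, t), signal_value(sig2, t)))
  }
  expect_error(generate_input_signal(1, -0.1), "positive")
  # constant signals really are constant
  expect_equal(diff(range(signal_value(generate_input_signal(2, 0.2,
                                                             "constant"), t))), 0)
})

test_that("scenarios survive a YAML round trip", {
  sc <- generate_scenario(77)
  path <- tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back$ic_original, sc$ic_original)
  expect_equal(back$ic_copy, sc$ic_copy)
  expect_equal(unclass(back$params), unclass(sc$params))
  t <- seq(0, 50, length.out = 100)
  expect_equal(signal_value(back$inputs$u1, t), signal_value(sc$inputs$u1, t))
  expect_equal(signal_value(back$inputs$u2, t), signal_value(sc$inputs$u2, t))
  expect_equal(kinetics_at(back$true_kin, t), kinetics_at(sc$true_kin, t))
  unlink(path)
})

test_that("random scenarios feed the whole pipeline without error", {
  # a thinned-down version of the 50-scenario property: every generated
  # bundle satisfies the preconditions of both analysis stages
  cases <- enumerate_cases()
  for (seed in 1:10) {
    sc <- generate_scenario(seed * 7L)
    cr <- cases[(seed %% 9) + 1, ]
    m <- case_model(cr, sc$params, sc$true_kin)
    red <- reduce_for_output(build_error_system(m, TRUE), m)
    cl <- classify_states(red, "generic")
    expect_s3_class(cl, "case_classification")
    traj <- simulate_pair(sc, m, TRUE, TRUE,
                          times = seq(sc$horizon[1], sc$horizon[2],
                                      length.out = 51))
    expect_false(anyNA(traj$eps1))
  }
})
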