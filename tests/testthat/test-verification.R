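test_that("identical systems from equal initial conditions show no error", {
  sc <- generate_scenario(55, equal_ic = TRUE, horizon = c(0, 20))
  m <- model_for_case(9)
  traj <- simulate_pair(sc, m, with_uncertainty = TRUE,
                        constrain_output = FALSE)
  expect_lt(max(abs(as.matrix(traj[, c("eps1", "eps2", "eps3")]))), 1e-8)
})

test_that("direct error integration equals the difference of independent runs", {
  times <- seq(0, 10, length.out = 101)
  for (case_id in c(1, 5, 9)) {
    m <- model_for_case(case_id)
    for (seed in 1:3) {
      sc <- generate_scenario(400 + seed, horizon = c(0, 10))
      traj <- simulate_pair(sc, m, with_uncertainty = TRUE,
                            constrain_output = FALSE, times = times)
      orig <- simulate_model(sc, model = m, ic = sc$ic_original, times = times)
      cop <- simulate_model(sc, model = m, ic = sc$ic_copy, times = times)
      diff_oracle <- as.matrix(orig[, 2:4]) - as.matrix(cop[, 2:4])
      expect_lt(max(abs(as.matrix(traj[, c("eps1", "eps2", "eps3")]) -
                          diff_oracle)), 1e-6)
    }
  }
})

test_that("constrained biomass error follows the closed-form envelope", {
  m <- model_for_case(1)
  red <- reduce_for_output(build_error_system(m, TRUE), m)
  times <- seq(0, 40, length.out = 161)
  for (seed in 1:3) {
    sc <- generate_scenario(500 + seed)
    traj <- simulate_pair(sc, m, TRUE, TRUE, times = times)
    gam <- closed_form_error(red, sc, times)
    expect_lt(max(abs(traj$eps1 - gam)) / max(abs(gam)), 1e-6)
  }
})

test_that("wash-out initial condition keeps biomass at zero throughout", {
  sc <- generate_scenario(61, washout = TRUE, horizon = c(0, 30))
  traj <- simulate_model(sc, times = seq(0, 30, length.out = 121))
  expect_lt(max(abs(traj$nu1)), 1e-10)
})

test_that("detectable labels pass and the envelope check rejects non-decay", {
  m <- model_for_case(1)
  red <- reduce_for_output(build_error_system(m, TRUE), m)
  cl <- classify_states(red, "generic")
  sc <- generate_scenario(71)
  tf <- horizon_for_tolerance(sc, tol = 1e-5)
  traj <- simulate_pair(sc, m, TRUE, TRUE,
                        times = seq(0, tf, length.out = 401))
  vc <- verify_convergence(traj, cl, tol = 1e-5)
  expect_true(all(vc$status[vc$label == "detectable"] == "pass"))
  expect_true(all(vc$status[vc$label == "measured"] == "not-checked"))
  # a truncated horizon must come back inconclusive, not pass
  short <- simulate_pair(sc, m, TRUE, TRUE, times = seq(0, 3, length.out = 31))
  vs <- verify_convergence(short, cl, tol = 1e-5)
  expect_true(any(vs$status == "inconclusive"))
  det <- vs[vs$label == "detectable", ]
  expect_false(any(det$status == "pass" & det$terminal_max > 1e-5))
})

test_that("states labelled not observable admit nonzero errors under equal outputs", {
  # case 1: substrate error starts nonzero and stays nonzero early on even
  # though the measured oxygen output of original and copy agree identically
  m <- model_for_case(1)
  found <- FALSE
  for (seed in 1:10) {
    sc <- generate_scenario(800 + seed)
    traj <- simulate_pair(sc, m, TRUE, TRUE,
                          times = seq(0, 5, length.out = 51))
    if (max(abs(traj$eps3)) < 1e-12 && abs(traj$eps2[1]) > 1e-3 &&
        all(abs(traj$eps2[1:10]) > 1e-4)) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("halving solver tolerances leaves terminal errors stable", {
  m <- model_for_case(6)
  sc <- generate_scenario(91)
  times <- seq(0, 60, length.out = 121)
  t1 <- simulate_pair(sc, m, TRUE, TRUE, times = times,
                      rtol = 1e-8, atol = 1e-10)
  t2 <- simulate_pair(sc, m, TRUE, TRUE, times = times,
                      rtol = 5e-9, atol = 5e-11)
  e1 <- abs(t1$eps1[nrow(t1)]); e2 <- abs(t2$eps1[nrow(t2)])
  expect_lt(abs(e1 - e2), 0.1 * max(e1, e2))
})
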