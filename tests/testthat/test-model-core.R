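test_that("ode_rhs reproduces the pool balance term by term", {
  inputs <- toy_inputs(glc = 100, pro = 50)

  # zero state, zero inputs -> zero derivative
  zero_in <- input_curves(c(0, 60), c(0, 0), c(0, 0))
  expect_equal(unname(ode_rhs(10, rep(0, 4), toy_rates(0.02), zero_in)),
               rep(0, 4))

  # single glycolytic term: k_GLY * C_glc
  p1 <- as_rate_params(stats::setNames(c(0.01, rep(0, 10)),
                                       postflux:::rate_names()))
  d1 <- ode_rhs(0, rep(0, 4), p1, toy_inputs(glc = 100, pro = 0))
  expect_equal(unname(d1), c(1, 0, 0, 0))

  # full rate set, hand evaluation:
  # dpyr = .01*100 + .01*20 + .01*5 - .04*10 = 0.85
  # dlac = .01*10 - .02*20 = -0.3
  # dala = .01*10 + .01*50 - .02*5 = 0.5
  # dcit = .01*10 - .01*1 = 0.09
  d <- ode_rhs(0, c(10, 20, 5, 1), toy_rates(0.01), inputs)
  expect_equal(unname(d), c(0.85, -0.3, 0.5, 0.09))

  expect_error(ode_rhs(0, c(NaN, 0, 0, 0), toy_rates(), inputs), "finite")
  expect_error(as_rate_params(stats::setNames(c(-0.1, rep(0.1, 10)),
                                              postflux:::rate_names())),
               "non-negative")
})

test_that("simulate_pools matches the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  params <- rate_params(k_GLY = 0.012, k_LDHf = 0.3, k_LDHb = 0.07,
                        k_ALTf = 0.11, k_ALTb = 0.04, k_TCA = 0.06,
                        k_Pro = 0.02, d_pyr = 0.05, d_lac = 0.04,
                        d_ala = 0.09, d_cit = 0.05)
  inputs <- toy_inputs(glc = 80, pro = 12)   # constant drivers
  y0 <- c(1, 2, 0.5, 0.1)
  times <- seq(0, 120, by = 10)
  traj <- simulate_pools(params, inputs, times, initial = y0)

  # independent affine closed form: y(t) = e^{At}(y0 + A^-1 b) - A^-1 b
  A <- postflux:::system_matrix(params)
  b <- c(params[["k_GLY"]] * 80, 0, params[["k_Pro"]] * 12, 0)
  Ainv_b <- solve(A, b)
  oracle <- t(sapply(times, function(t) {
    as.numeric(Matrix::expm(A * t) %*% (y0 + Ainv_b) - Ainv_b)
  }))
  expect_lt(max(abs(traj$states - oracle) / pmax(abs(oracle), 1e-12)), 1e-6)
})

test_that("simulated pools obey balance, linearity and non-negativity", {
  params <- rate_params(k_GLY = 0.01, k_LDHf = 0.25, k_LDHb = 0.06,
                        k_ALTf = 0.1, k_ALTb = 0.05, k_TCA = 0.04,
                        k_Pro = 0.015, d_pyr = 0.06, d_lac = 0.05,
                        d_ala = 0.08, d_cit = 0.03)
  inputs <- input_curves(c(0, 30, 60, 120, 240),
                         c(0, 60, 80, 30, 5), c(0, 4, 8, 6, 1))

  # no dynamics: all rates zero
  traj0 <- simulate_pools(toy_rates(0), inputs, c(0, 50, 100),
                          initial = c(1, 1, 1, 1))
  expect_equal(unname(traj0$states), matrix(1, 3, 4))

  # pool balance: d/dt sum(C) = k_GLY C_glc + k_Pro C_pro - sum(d_i C_i),
  # checked by central differences of the simulated summed pools
  times <- seq(0, 240, by = 5)
  h <- 1e-3
  traj <- simulate_pools(params, inputs, times)
  for (tt in c(10, 45, 100, 200)) {
    tr <- simulate_pools(params, inputs, c(0, tt - h, tt, tt + h))
    dsum <- (sum(tr$states[4, ]) - sum(tr$states[2, ])) / (2 * h)
    u <- eval_inputs(inputs, tt)
    st <- tr$states[3, ]
    expected <- params[["k_GLY"]] * u$glc + params[["k_Pro"]] * u$pro -
      params[["d_pyr"]] * st["pyr"] - params[["d_lac"]] * st["lac"] -
      params[["d_ala"]] * st["ala"] - params[["d_cit"]] * st["cit"]
    expect_equal(dsum, unname(expected), tolerance = 1e-6)
  }

  # linearity in state and forcing
  inputs2 <- input_curves(inputs$time, 2 * inputs$glc, 2 * inputs$pro)
  tr1 <- simulate_pools(params, inputs, times, initial = c(1, 0, 2, 0))
  tr2 <- simulate_pools(params, inputs2, times, initial = 2 * c(1, 0, 2, 0))
  expect_equal(tr2$states, 2 * tr1$states, tolerance = 1e-10)

  # non-negativity across random rate draws
  set.seed(42)
  for (i in 1:20) {
    p <- as_rate_params(stats::setNames(10^stats::runif(11, -4, 0),
                                        postflux:::rate_names()))
    tr <- simulate_pools(p, inputs, times)
    expect_gte(min(tr$states), -1e-10)
  }
})

test_that("input curves interpolate linearly and clamp outside the grid", {
  ic <- input_curves(c(0, 60, 120), c(0, 100, 40), c(0, 10, 2))
  u <- eval_inputs(ic, c(-30, 0, 30, 60, 90, 120, 400))
  expect_equal(u$glc, c(0, 0, 50, 100, 70, 40, 40))
  expect_equal(u$pro, c(0, 0, 5, 10, 6, 2, 2))
  expect_error(input_curves(c(0, 0, 60), c(1, 1, 1)), "strictly increasing")
  expect_error(input_curves(c(0, 60), c(-1, 1)), "non-negative")
})

test_that("blood scaling follows the breakpoint schedule and round-trips", {
  sched <- scaling_schedule(s_pa = 1, s_a = 2)
  # interpolation identities at and between breakpoints
  expect_equal(eval_scaling(sched, c(0, 60, 120, 240, 360)),
               c(1, 1.5, 2, 1.5, 1))
  # clamped outside
  expect_equal(eval_scaling(sched, c(-60, 400)), c(1, 1))

  params <- toy_rates(0.05)
  traj <- simulate_pools(params, toy_inputs(), seq(0, 120, 30),
                         initial = c(1, 1, 1, 1))
  blood <- to_blood(traj, sched)
  expect_equal(blood$scale, "blood")
  expect_equal(blood$states, traj$states * eval_scaling(sched, traj$times))
  expect_error(to_blood(blood, sched), "already blood")
  back <- to_intracellular(blood, sched)
  expect_equal(back$states, traj$states)

  # unit schedule is the identity
  unit <- to_blood(traj, scaling_schedule(1, 1))
  expect_equal(unit$states, traj$states)
})

test_that("rate parameter sets serialise and validate", {
  p <- toy_rates(0.03)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  write_rate_params(p, csv)
  write_rate_params(p, json)
  expect_equal(unclass(read_rate_params(csv)), unclass(p))
  expect_equal(unclass(read_rate_params(json)), unclass(p))
  expect_error(as_rate_params(c(k_GLY = 1)), "rate names")
})
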