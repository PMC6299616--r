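test_that("hill function matches closed form and rejects bad input", {
  expect_identical(hill(0, 5, 2), 0)
  expect_equal(hill(5, 5, 2), 0.5)
  expect_equal(hill(50, 5, 2), 2500 / (25 + 2500), tolerance = 1e-12)
  # monotone nondecreasing
  u <- seq(0, 100, by = 0.5)
  expect_true(all(diff(hill(u, 7, 3)) >= 0))
  expect_error(hill(1, -1, 2), "half")
  expect_error(hill(1, 5, 0.5), "exponent")
  expect_error(hill(NaN, 5, 2), "non-finite")
})

test_that("suppression factor matches closed form", {
  expect_equal(suppression(0, 3), 1)
  expect_equal(suppression(3, 3), 0.5)
  expect_equal(suppression(6, 3), 0.2)
  expect_error(suppression(1, 0), "a_inf")
})

test_that("rate expressions at the all-zero state collapse correctly", {
  p <- ARCHES$cluster1$params
  zero <- setNames(rep(0, 7), state_names())
  r <- model_rates(zero, p)
  expect_equal(r$Rm1, 0)
  expect_equal(r$Rm2, 0)
  expect_equal(r$Rms, 0)
  expect_equal(r$Rp, 0)
  expect_equal(r$Ra, 0)
  expect_equal(r$Rt, p[["k_tbase"]])
  expect_equal(r$mr, p[["s_mr"]] / p[["mu_mr"]])
})

test_that("rate outputs respect their analytic bounds on random inputs", {
  set.seed(41)
  for (i in 1:50) {
    p <- random_params()
    s <- random_state()
    r <- model_rates(s, p)
    expect_true(r$Rm1 >= 0 && r$Rm1 <= 1)
    expect_true(r$Rm2 >= 0 && r$Rm2 <= 1)
    expect_true(r$Rms >= 0 && r$Rms <= 1)
    expect_lte(r$Rp, s[["M1"]] * (p[["k_M1base"]] + 1))
    expect_lte(r$Ra, s[["M2"]] * (p[["k_M2base"]] + 1))
    expect_lte(r$Rt, p[["k_tbase"]] + 1)
    expect_true(r$mr > 0 && r$mr <= p[["s_mr"]] / p[["mu_mr"]])
  }
})

test_that("rhs agrees with an independent transcription to 1e-12", {
  set.seed(42)
  for (i in 1:100) {
    p <- random_params()
    s <- random_state()
    got <- model_rhs(s, p)
    want <- oracle_rhs(s, p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("rhs at the origin equals its closed form exactly", {
  p <- ARCHES$cluster2B$params
  zero <- setNames(rep(0, 7), state_names())
  d <- model_rhs(zero, p)
  expect_identical(unname(d[c("M1", "M2", "IL1", "IL12", "D")]),
                   rep(0, 5))
  expect_equal(d[["IL10"]], p[["k_tn10"]] * p[["k_tbase"]])
  expect_equal(d[["IL4"]], p[["k_tn4"]] * p[["k_tbase"]])
})

test_that("zeroed state components never receive negative derivatives", {
  set.seed(43)
  for (i in 1:20) {
    p <- random_params()
    s <- random_state()
    comp <- state_names()[sample(7, 1)]
    s[comp] <- 0
    expect_gte(model_rhs(s, p)[[comp]], 0)
  }
})

test_that("production-free model decays as a pure exponential", {
  p <- pure_decay_params(mu_M1 = 0.07)
  init <- c(M1 = 12, M2 = 0, IL1 = 0, IL12 = 0, IL10 = 0, IL4 = 0, D = 0)
  tt <- seq(0, 120, by = 2)
  traj <- simulate_model(p, init, times = tt, validate = FALSE)
  expect_equal(traj$M1, 12 * exp(-0.07 * tt), tolerance = 1e-5)
  expect_true(all(traj[, c("M2", "IL1", "IL12", "IL10", "IL4")] < 1e-6))
})

test_that("adaptive solver agrees with a fixed-step RK4 oracle", {
  set.seed(44)
  tt <- seq(0, 120, by = 12)
  for (i in 1:20) {
    a <- ARCHES[[sample(length(ARCHES), 1)]]
    p <- a$params * stats::runif(45, 0.85, 1.15)
    p[hill_exponent_names()] <- pmax(p[hill_exponent_names()], 1)
    init <- a$init * stats::runif(7, 0.85, 1.15)
    traj <- simulate_model(p, init, times = tt, rtol = 1e-8, atol = 1e-10)
    ref <- oracle_rk4(p, init, tt, dt = 0.01)
    got <- as.matrix(traj[, state_names()])
    rel <- abs(got - ref) / pmax(abs(ref), 1e-3)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("states stay nonnegative over the full horizon (forward invariance)", {
  set.seed(45)
  for (i in 1:20) {
    p <- random_params()
    init <- random_state()
    traj <- simulate_model(p, init, times = seq(0, 120, by = 2))
    expect_true(all(as.matrix(traj[, state_names()]) >= 0))
  }
})

test_that("raising IL-10 never increases the suppressed production rates", {
  set.seed(46)
  for (i in 1:10) {
    p <- random_params()
    s <- random_state()
    il10 <- seq(0, 100, by = 5)
    vals <- t(vapply(il10, function(v) {
      s[["IL10"]] <- v
      r <- model_rates(s, p)
      dd_cyt <- (p[["alpha_n12"]] * s[["IL12"]] + p[["alpha_n1"]] * s[["IL1"]]) *
        suppression(v, p[["a_inf2"]])
      c(r$Rp, r$Rt, r$Ra, dd_cyt)
    }, numeric(4)))
    expect_true(all(diff(vals[, 1]) <= 1e-12))
    expect_true(all(diff(vals[, 2]) <= 1e-12))
    expect_true(all(diff(vals[, 3]) <= 1e-12))
    expect_true(all(diff(vals[, 4]) <= 1e-12))
  }
})

test_that("trajectories carry their provenance and start at the initial state", {
  a <- ARCHES$cluster1
  traj <- simulate_model(a$params, a$init, times = seq(0, 48, by = 6))
  expect_equal(traj$time_h[1], 0)
  expect_equal(unlist(traj[1, state_names()]), a$init,
               ignore_attr = TRUE)
  expect_equal(attr(traj, "params"), a$params)
  expect_equal(attr(traj, "init"), a$init)
  expect_error(simulate_model(a$params, a$init, times = c(6, 12)),
               "start at 0")
})

test_that("quasi-steady-state resting pool tracks the full dynamic variant", {
  a <- ARCHES$cluster1
  tt <- seq(0, 120, by = 6)
  qss <- simulate_model(a$params, a$init, times = tt)
  full <- simulate_model_full_mr(a$params, a$init, times = tt)
  # fast resting turnover: the reduction should track within a few percent
  rel <- abs(qss$M1 - full$M1) / pmax(full$M1, 1)
  expect_lt(max(rel), 0.05)
})
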