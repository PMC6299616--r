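test_that("optimizer-space encoding round-trips and floors exponents", {
  a <- ARCHES$cluster2A
  th <- encode_theta(a$params, a$init)
  dec <- decode_theta(th)
  expect_equal(dec$params, a$params, tolerance = 1e-12)
  expect_equal(dec$init, a$init, tolerance = 1e-10)

  # the log-space origin decodes to all-ones (exponent floor idle at 1)
  dec0 <- decode_theta(rep(0, 52))
  expect_true(all(dec0$params == 1))
  expect_equal(unname(dec0$init), rep(1 - 1e-6, 7))

  # a large negative exponent entry is floored at 1
  th_bad <- th
  th_bad[match("x_n", param_names())] <- -30
  expect_equal(decode_theta(th_bad)$params[["x_n"]], 1)
  expect_error(decode_theta(rep(NA_real_, 52)), "finite")
})

test_that("the data term reproduces hand-computed chi-square arithmetic", {
  a <- ARCHES$cluster1
  th <- encode_theta(a$params, a$init)
  # means offset from the model by -2 and +2 with SDs 2 and 4:
  # (model - mean)^2 / sd^2 = 4/4 + 4/16 = 1.25 per analyte
  traj <- simulate_model(a$params, a$init, times = seq(0, 120, by = 1))
  v <- traj$IL10[match(c(6, 12), traj$time_h)]
  binned <- data.frame(analyte = "IL10", bin_center_h = c(6, 12),
                       mean = v + c(-2, 2), sd = c(2, 4), se = c(1, 2),
                       n = c(4, 4))
  opts <- fit_opts(penalty = 0)
  expect_equal(fit_objective(th, binned, opts), 1.25, tolerance = 1e-9)
  d <- fit_objective(th, binned, fit_opts(), details = TRUE)
  expect_equal(d$data_term, 1.25, tolerance = 1e-9)
  expect_equal(d$error - d$data_term, 100 * sum(d$penalty_flags))
})

test_that("a model matching every bin mean has zero data error", {
  a <- ARCHES$cluster1
  binned <- manufactured_binned(a$params, a$init)
  d <- fit_objective(encode_theta(a$params, a$init), binned, fit_opts(),
                     details = TRUE)
  expect_equal(d$data_term, 0)
})

test_that("each violated microglia heuristic adds a flat 100", {
  # negligible microglia (<= 2 everywhere); M2 starts above M1, violating
  # early M1 dominance, but decays faster (mu_M2 > mu_M1) and crosses
  # below M1 before the late window -> all three heuristics violated
  p <- pure_decay_params(mu_M1 = 0.05)
  init <- c(M1 = 0.5, M2 = 1, IL1 = 0, IL12 = 0, IL10 = 0, IL4 = 0, D = 0)
  empty <- data.frame(analyte = "IL1b", bin_center_h = 6, mean = NA_real_,
                      sd = NA_real_, se = NA_real_, n = 0L)
  th <- c(log(p), log(init + 1e-6))
  d <- fit_objective(th, empty, fit_opts(), details = TRUE)
  expect_equal(d$data_term, 0)
  expect_true(all(d$penalty_flags))
  expect_equal(d$error, 300)
})

test_that("objective is invariant to bin and analyte ordering and to
           rescaling a bin's residual scale", {
  a <- ARCHES$cluster2B
  th <- encode_theta(a$params, a$init)
  binned <- manufactured_binned(a$params, a$init, offset = 0.5)
  v0 <- fit_objective(th, binned, fit_opts())
  shuf <- binned[sample(nrow(binned)), ]
  expect_equal(fit_objective(th, shuf, fit_opts()), v0)
  # scaling one bin's (deviation, sd) by c leaves its contribution fixed
  traj <- simulate_model(a$params, a$init, times = seq(0, 120, by = 1))
  i <- which(binned$analyte == "IL12" & binned$bin_center_h == 18)
  model_v <- traj$IL12[match(18, traj$time_h)]
  scaled <- binned
  scaled$mean[i] <- model_v - 3 * (model_v - binned$mean[i])
  scaled$sd[i] <- 3 * binned$sd[i]
  expect_equal(fit_objective(th, scaled, fit_opts()), v0)
})

test_that("fitting from a zero-error start returns it unchanged", {
  a <- ARCHES$cluster1
  binned <- manufactured_binned(a$params, a$init)
  mask <- rep(FALSE, 52)
  mask[match(c("mu_M1", "k_pn1", "b_n"), param_names())] <- TRUE
  ft <- fit_model(list(params = a$params, init = a$init), binned,
                  fit_opts(mask = mask, max_iter = 50, penalty = 0))
  expect_equal(ft$error, 0)
  expect_equal(ft$params, a$params, tolerance = 1e-12)
})

test_that("the evaluation cap is honored and flagged", {
  a <- ARCHES$cluster1
  binned <- manufactured_binned(a$params, a$init)
  ft <- fit_model(list(params = a$params, init = a$init), binned,
                  fit_opts(max_evals = 1))
  expect_false(ft$converged)
  expect_equal(ft$n_evals, 1L)
  expect_equal(ft$params, a$params, tolerance = 1e-12)
})

test_that("the refit never ends worse than its start", {
  set.seed(9)
  a <- ARCHES$cluster2A
  binned <- manufactured_binned(a$params, a$init, offset = 0.3)
  start <- perturb_start(a$params, a$init)
  th0 <- encode_theta(start$params, start$init)
  v0 <- fit_objective(th0, binned, fit_opts())
  ft <- fit_model(start, binned, fit_opts(max_iter = 40, max_evals = 120))
  expect_lte(ft$error, v0)
})

test_that("a restricted free-parameter fit recovers the truth within 10%", {
  a <- ARCHES$cluster1
  binned <- manufactured_binned(a$params, a$init, sd_frac = 0.1)
  free <- c("mu_M1", "k_pn1", "a_inf2")
  start_p <- a$params
  start_p[free] <- start_p[free] * 1.2
  mask <- rep(FALSE, 52)
  mask[match(free, param_names())] <- TRUE
  ft <- fit_model(list(params = start_p, init = a$init), binned,
                  fit_opts(mask = mask, max_iter = 400, tol_f = 1e-10))
  rel <- abs(ft$params[free] - a$params[free]) / a$params[free]
  expect_true(all(rel < 0.10))
  expect_lt(ft$data_term, 1e-2)
})
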