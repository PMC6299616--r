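#' Hill activation function
#'
#' Saturating response `u^n / (half^n + u^n)`, monotone nondecreasing in
#' `u`, with half-activation constant `half` and Hill coefficient
#' `exponent`. Evaluated as `1 / (1 + (half/u)^exponent)` for `u > 0`,
#' which is overflow-safe for large arguments or exponents.
#'
#' @param u Nonnegative signal level.
#' @param half Half-activation constant, > 0.
#' @param exponent Hill coefficient, >= 1.
#' @return Value in `[0, 1)`.
#' @examples
#' hill(5, 5, 2)   # 0.5 at half-activation
#' @export
hill <- function(u, half, exponent) {
  if (!all(is.finite(u)) || !all(is.finite(half)) || !all(is.finite(exponent))) {
    stop("non-finite argument to hill()", call. = FALSE)
  }
  if (any(half <= 0)) stop("`half` must be > 0", call. = FALSE)
  if (any(exponent < 1)) stop("`exponent` must be >= 1", call. = FALSE)
  if (any(u < 0)) stop("`u` must be nonnegative", call. = FALSE)
  ifelse(u > 0, 1 / (1 + (half / u)^exponent), 0)
}

#' Quadratic suppression factor
#'
#' Inhibition term `1 / (1 + (level/a_inf)^2)` used for the
#' anti-inflammatory damping of M1 polarization, pro-inflammatory
#' production, Th2 release and damage induction. Equals 1 at `level = 0`
#' and decreases strictly in `level`.
#'
#' @param level Nonnegative inhibitor level.
#' @param a_inf Threshold-like factor, > 0.
#' @return Value in `(0, 1]`.
#' @export
suppression <- function(level, a_inf) {
  if (!all(is.finite(level)) || !all(is.finite(a_inf))) {
    stop("non-finite argument to suppression()", call. = FALSE)
  }
  if (any(a_inf <= 0)) stop("`a_inf` must be > 0", call. = FALSE)
  if (any(level < 0)) stop("`level` must be nonnegative", call. = FALSE)
  1 / (1 + (level / a_inf)^2)
}

# Core rate expressions; assumes already-validated inputs (internal hot path).
rate_terms <- function(state, params) {
  p <- params
  M1 <- state[["M1"]]; M2 <- state[["M2"]]
  IL1 <- state[["IL1"]]; IL12 <- state[["IL12"]]
  IL10 <- state[["IL10"]]; IL4 <- state[["IL4"]]
  D <- state[["D"]]

  sup1 <- 1 / (1 + ((IL10 + IL4) / p[["a_inf1"]])^2)
  sup2 <- 1 / (1 + (IL10 / p[["a_inf2"]])^2)

  h <- function(u, half, n) if (u > 0) 1 / (1 + (half / u)^n) else 0

  Rm1 <- h(p[["k_n1"]] * IL1 + p[["k_n12"]] * IL12, p[["b_n"]], p[["x_n"]]) * sup1
  Rm2 <- h(p[["k_n4"]] * IL4 + p[["k_n10"]] * IL10, p[["y_n"]], p[["z_n"]])
  Rms <- h(p[["tau_n4"]] * IL4 + p[["tau_n10"]] * IL10, p[["m_n"]], p[["g_n"]])
  Rp <- (p[["k_M1base"]] * M1 +
           M1 * h(IL12 + p[["kcd"]] * D, p[["v_n"]], p[["h_n"]])) * sup1
  Rt <- (p[["k_tbase"]] +
           h(IL4 + p[["k_tn12"]] * IL12, p[["r_n"]], p[["c_n"]])) * sup2
  Ra <- (p[["k_M2base"]] * M2 +
           M2 * h(p[["kc4"]] * IL4, p[["w_n"]], p[["q_n"]])) * sup2
  mr <- p[["s_mr"]] / (Rm1 + Rm2 + p[["mu_mr"]])

  list(Rm1 = Rm1, Rm2 = Rm2, Rms = Rms, Rp = Rp, Rt = Rt, Ra = Ra,
       mr = mr, sup2 = sup2)
}

#' Model rate expressions
#'
#' Evaluates the six composite rate expressions of the neuroinflammation
#' network and the quasi-steady-state resting microglia level at one
#' state:
#' \itemize{
#'   \item `Rm1`, `Rm2`: cytokine-driven activation of resting microglia
#'     to the M1-/M2-like state (Hill responses to the pro- and
#'     anti-inflammatory cytokine pools; `Rm1` is damped by IL-10 + IL-4).
#'   \item `Rms`: the IL-4/IL-10-driven M1-to-M2 phenotype switch.
#'   \item `Rp`: pro-inflammatory cytokine production by M1 (baseline plus
#'     IL-12/damage-DAMP promotion, damped by IL-10 + IL-4).
#'   \item `Rt`: Th2-mediated cytokine release (baseline plus IL-4/IL-12
#'     signaling, self-limited by IL-10).
#'   \item `Ra`: anti-inflammatory production by M2 (baseline plus
#'     IL-4 promotion, self-limited by IL-10).
#'   \item `mr`: resting microglia at quasi-steady state,
#'     `s_mr / (Rm1 + Rm2 + mu_mr)`.
#' }
#'
#' @param state Named state vector, see [state_names()].
#' @param params Named parameter vector, see [param_names()].
#' @return Named list with components `Rm1`, `Rm2`, `Rms`, `Rp`, `Rt`,
#'   `Ra`, `mr`.
#' @export
model_rates <- function(state, params) {
  state <- validate_state(state)
  params <- validate_params(params)
  rate_terms(state, params)[c("Rm1", "Rm2", "Rms", "Rp", "Rt", "Ra", "mr")]
}

# Derivative vector; assumes validated inputs.
rhs_core <- function(state, params) {
  p <- params
  r <- rate_terms(state, params)
  M1 <- state[["M1"]]; M2 <- state[["M2"]]
  IL1 <- state[["IL1"]]; IL12 <- state[["IL12"]]
  IL10 <- state[["IL10"]]; IL4 <- state[["IL4"]]
  D <- state[["D"]]
  c(
    M1 = r$Rm1 * r$mr - r$Rms * M1 - p[["mu_M1"]] * M1,
    M2 = r$Rm2 * r$mr + r$Rms * M1 - p[["mu_M2"]] * M2,
    IL1 = p[["k_pn1"]] * r$Rp - p[["mu_n1"]] * IL1,
    IL12 = p[["k_pn12"]] * r$Rp - p[["mu_n12"]] * IL12,
    IL10 = p[["k_tn10"]] * r$Rt + p[["k_pn10"]] * r$Ra - p[["mu_n10"]] * IL10,
    IL4 = p[["k_tn4"]] * r$Rt + p[["k_pn4"]] * r$Ra - p[["mu_n4"]] * IL4,
    D = (p[["alpha_n12"]] * IL12 + p[["alpha_n1"]] * IL1) * r$sup2 +
      p[["r_M1"]] * M1 - p[["gamma_M1"]] * M1 * D - p[["gamma_M2"]] * M2 * D
  )
}

#' Model right-hand side
#'
#' Time derivatives of the seven state variables. The system is
#' autonomous; `t` is accepted for interface compatibility and ignored.
#'
#' @param state Named state vector.
#' @param params Named parameter vector.
#' @param t Time (h), unused.
#' @return Named numeric vector of derivatives in [state_names()] order.
#' @export
model_rhs <- function(state, params, t = 0) {
  state <- validate_state(state)
  params <- validate_params(params)
  rhs_core(state, params)
}

solver_failure <- function(msg, time = NA_real_) {
  stop(errorCondition(paste0("solver failure at t = ", format(time), ": ", msg),
                      time = time,
                      class = c("tbinflam_solver_failure", "error")))
}

#' Simulate the neuroinflammation model
#'
#' Integrates the seven-state system over `times` with a stiff-capable
#' adaptive solver (deSolve's `lsoda` by default). States that undershoot
#' zero by no more than `atol` are clipped to zero after integration;
#' larger negative excursions, non-finite states, or early solver
#' termination raise a solver-failure condition (class
#' `tbinflam_solver_failure`) carrying the failing time.
#'
#' @param params Named parameter vector (45 entries).
#' @param init Named initial state (7 entries, nonnegative).
#' @param times Increasing time grid in hours starting at 0.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param method deSolve integration method (default `"lsoda"`).
#' @param validate Set `FALSE` to skip input validation on hot paths.
#' @return A data frame with columns `time_h`, `M1`, `M2`, `IL1`, `IL12`,
#'   `IL10`, `IL4`, `D` and attributes `params` and `init` recording the
#'   inputs (a trajectory).
#' @export
simulate_model <- function(params, init, times = seq(0, 120, by = 1),
                           rtol = 1e-6, atol = 1e-9, method = "lsoda",
                           validate = TRUE) {
  if (validate) {
    params <- validate_params(params)
    init <- validate_state(init)
  }
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be increasing and start at 0", call. = FALSE)
  }
  derivs <- function(t, y, parms) list(rhs_core(y, parms))
  out <- tryCatch(
    suppressWarnings(
      deSolve::ode(y = init, times = times, func = derivs, parms = params,
                   method = method, rtol = rtol, atol = atol)
    ),
    error = function(e) solver_failure(conditionMessage(e))
  )
  out <- as.matrix(out)
  if (nrow(out) < length(times)) {
    solver_failure("integration stopped early",
                   time = out[nrow(out), "time"])
  }
  ystates <- out[, state_names(), drop = FALSE]
  if (any(!is.finite(ystates))) {
    bad <- which(!is.finite(rowSums(ystates)))[1]
    solver_failure("non-finite state", time = out[bad, "time"])
  }
  if (any(ystates < -atol)) {
    bad <- which(apply(ystates, 1, min) < -atol)[1]
    solver_failure(sprintf("state below -atol (min %.3e)", min(ystates)),
                   time = out[bad, "time"])
  }
  ystates[ystates < 0] <- 0
  traj <- data.frame(time_h = out[, "time"], ystates)
  attr(traj, "params") <- params
  attr(traj, "init") <- init
  traj
}

#' Simulate with an explicit resting-microglia state
#'
#' Integrates the eight-state variant in which resting microglia `mr`
#' evolve by their full balance equation
#' `dmr/dt = s_mr - (Rm1 + Rm2 + mu_mr) * mr` instead of the
#' quasi-steady-state expression used everywhere else. Provided to check
#' self-consistency of the quasi-steady-state reduction; not used by the
#' fitting pipeline.
#'
#' @inheritParams simulate_model
#' @param mr0 Initial resting microglia level; defaults to the
#'   quasi-steady-state value at `init`.
#' @return Data frame like [simulate_model()] with an extra `mr` column.
#' @export
simulate_model_full_mr <- function(params, init, times = seq(0, 120, by = 1),
                                   mr0 = NULL, rtol = 1e-6, atol = 1e-9) {
  params <- validate_params(params)
  init <- validate_state(init)
  if (is.null(mr0)) {
    mr0 <- rate_terms(init, params)$mr
  }
  y0 <- c(init, mr = mr0)
  derivs <- function(t, y, p) {
    st <- y[state_names()]
    r <- rate_terms(st, p)
    d <- rhs_core(st, p)
    # replace quasi-steady mr by the dynamic value in the microglia terms
    d[["M1"]] <- r$Rm1 * y[["mr"]] - r$Rms * st[["M1"]] - p[["mu_M1"]] * st[["M1"]]
    d[["M2"]] <- r$Rm2 * y[["mr"]] + r$Rms * st[["M1"]] - p[["mu_M2"]] * st[["M2"]]
    dmr <- p[["s_mr"]] - (r$Rm1 + r$Rm2 + p[["mu_mr"]]) * y[["mr"]]
    list(c(d, mr = dmr))
  }
  out <- as.data.frame(deSolve::ode(y = y0, times = times, func = derivs,
                                    parms = params, method = "lsoda",
                                    rtol = rtol, atol = atol))
  names(out)[1] <- "time_h"
  out
}

#' Write a trajectory to CSV
#'
#' Columns `time_h, M1, M2, IL1, IL12, IL10, IL4, D`.
#'
#' @param traj Trajectory from [simulate_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
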