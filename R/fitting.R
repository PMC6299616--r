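#' Fitting options
#'
#' Options controlling the penalized objective and the simplex search.
#'
#' @param max_iter Maximum simplex iterations (default 5000).
#' @param max_evals Hard cap on objective evaluations (default 10000).
#' @param tol_f Relative convergence tolerance on the objective
#'   (default 1e-6).
#' @param tol_x Tolerance on the optimizer-space vector, recorded for
#'   provenance; the simplex itself stops on `tol_f`.
#' @param sd_floor Bins with pooled SD at or below this value are skipped
#'   by the data term (default 0, i.e. only SD = 0 and n < 2 bins skip).
#' @param heuristic_grid_h Spacing of the time grid on which the
#'   microglia heuristics are checked (default 1 h).
#' @param penalty Flat penalty added per violated microglia heuristic
#'   (default 100).
#' @param mask Logical vector of length 52 (45 parameters then 7 initial
#'   conditions) marking free coordinates; `NULL` frees all.
#' @param sentinel Objective value returned when integration fails
#'   (default 1e10).
#' @param rtol,atol Integration tolerances used inside the objective.
#' @return A list of class `tbinflam_fit_opts`.
#' @export
fit_opts <- function(max_iter = 5000, max_evals = 10000, tol_f = 1e-6,
                     tol_x = 1e-6, sd_floor = 0, heuristic_grid_h = 1,
                     penalty = 100, mask = NULL, sentinel = 1e10,
                     rtol = 1e-6, atol = 1e-9) {
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), length(mask) == 52, !anyNA(mask))
  }
  structure(list(max_iter = max_iter, max_evals = max_evals, tol_f = tol_f,
                 tol_x = tol_x, sd_floor = sd_floor,
                 heuristic_grid_h = heuristic_grid_h, penalty = penalty,
                 mask = mask, sentinel = sentinel, rtol = rtol, atol = atol),
            class = "tbinflam_fit_opts")
}

IC_OFFSET <- 1e-6

#' Encode / decode the optimizer vector
#'
#' The 45 parameters and 7 initial conditions are optimized in log space
#' so that any real 52-vector decodes to a positive parameter set
#' (positivity is a biological requirement). Initial conditions are
#' log-transformed with a small offset (1e-6) so exact-zero starts are
#' admissible. On decoding, Hill exponents are floored at 1.
#' `decode_theta(encode_theta(p, s))` reproduces its input to relative
#' 1e-12 whenever the input satisfies the invariants.
#'
#' @param params Named parameter vector (45 entries, positive).
#' @param init Named initial state (7 entries, nonnegative).
#' @param theta Numeric vector of length 52 (parameters then initial
#'   conditions, in [param_names()] / [state_names()] order).
#' @return `encode_theta()`: a named numeric 52-vector.
#'   `decode_theta()`: a list with components `params` and `init`.
#' @export
encode_theta <- function(params, init) {
  params <- validate_params(params)
  init <- validate_state(init)
  theta <- c(log(params), log(init + IC_OFFSET))
  if (any(!is.finite(theta))) stop("non-finite encoding", call. = FALSE)
  names(theta) <- c(param_names(), paste0("init_", state_names()))
  theta
}

#' @rdname encode_theta
#' @export
decode_theta <- function(theta) {
  if (length(theta) != 52 || any(!is.finite(theta))) {
    stop("`theta` must be a finite 52-vector", call. = FALSE)
  }
  params <- exp(theta[1:45])
  names(params) <- param_names()
  he <- hill_exponent_names()
  params[he] <- pmax(params[he], 1)
  init <- pmax(exp(theta[46:52]) - IC_OFFSET, 0)
  names(init) <- state_names()
  list(params = params, init = init)
}

# Data term + heuristic penalties on one simulated trajectory.
# `binned` rows with n >= 2 and sd > sd_floor enter the data term.
objective_from_traj <- function(traj, binned, opts) {
  amap <- analyte_states()
  usable <- binned$n >= 2 & is.finite(binned$sd) & binned$sd > opts$sd_floor
  data_term <- 0
  for (i in which(usable)) {
    st <- amap[[binned$analyte[i]]]
    idx <- match(binned$bin_center_h[i], traj$time_h)
    if (is.na(idx)) {
      stop("trajectory grid does not contain bin center ",
           binned$bin_center_h[i], call. = FALSE)
    }
    data_term <- data_term +
      (traj[[st]][idx] - binned$mean[i])^2 / binned$sd[i]^2
  }
  tt <- traj$time_h
  early <- tt >= 0 & tt < 48
  late <- tt > 72 & tt <= 120
  flags <- c(
    early_m1_dominance = any(traj$M1[early] <= traj$M2[early]),
    late_m2_dominance = any(traj$M2[late] <= traj$M1[late]),
    microglia_floor = any(pmin(traj$M1, traj$M2) <= 2)
  )
  list(error = data_term + opts$penalty * sum(flags),
       data_term = data_term, penalty_flags = flags)
}

# Time grid covering the heuristic checks and all usable bin centers.
objective_grid <- function(opts) {
  sort(unique(c(seq(0, 120, by = opts$heuristic_grid_h), bin_centers())))
}

#' Penalized fitting objective
#'
#' Decodes `theta`, simulates the model over \[0, 120\] h, and returns the
#' sum over the four cytokines and all usable moving-average bins of
#' `(model at bin center - bin mean)^2 / sd^2`, plus a flat penalty
#' (default 100) for each violated microglia heuristic: M1 > M2 before
#' day 2 (checked on \[0, 48) h), M2 > M1 after day 3 (checked on
#' (72, 120\] h), and M1, M2 > 2 over the whole time course. Heuristics
#' are checked on a 1-h grid by default. Bins with fewer than two
#' measurements or SD at the floor are skipped. Integration failure
#' returns the sentinel value (1e10) rather than raising, so the simplex
#' can move away from pathological parameter regions.
#'
#' @param theta Optimizer-space 52-vector (see [encode_theta()]).
#' @param binned Binned series from [bin_series()].
#' @param opts Options from [fit_opts()].
#' @param details If `TRUE`, return a list with `error`, `data_term` and
#'   `penalty_flags` instead of the bare value.
#' @return Scalar objective value (or a detail list).
#' @export
fit_objective <- function(theta, binned, opts = fit_opts(), details = FALSE) {
  dec <- decode_theta(theta)
  res <- tryCatch({
    traj <- simulate_model(dec$params, dec$init, times = objective_grid(opts),
                           rtol = opts$rtol, atol = opts$atol,
                           validate = FALSE)
    objective_from_traj(traj, binned, opts)
  },
  tbinflam_solver_failure = function(e) {
    list(error = opts$sentinel, data_term = opts$sentinel,
         penalty_flags = c(early_m1_dominance = NA, late_m2_dominance = NA,
                           microglia_floor = NA))
  })
  if (details) res else res$error
}

#' Fit the model to a binned cytokine series
#'
#' Nelder-Mead simplex minimization (standard reflection/expansion/
#' contraction/shrink coefficients 1, 2, 0.5, 0.5, via [stats::optim()])
#' of the penalized objective over the log-transformed 45 parameters and
#' 7 initial conditions. A free/fixed mask restricts the search to a
#' subset of coordinates. The best evaluated point is tracked explicitly
#' so the returned fit is never worse than the start, and a hard
#' `max_evals` cap is honored even mid-iteration. Deterministic given
#' `start` and `opts`; optimizer non-convergence is flagged, never
#' raised.
#'
#' @param start List with `params` and `init` (the starting point), or a
#'   `tbinflam_fit` whose solution is reused as a start.
#' @param binned Binned series from [bin_series()].
#' @param opts Options from [fit_opts()].
#' @return A list of class `tbinflam_fit`: `params`, `init`, `error`,
#'   `data_term`, `penalty_flags`, `converged`, `n_evals`, `start`,
#'   `opts`.
#' @export
fit_model <- function(start, binned, opts = fit_opts()) {
  if (inherits(start, "tbinflam_fit")) {
    start <- list(params = start$params, init = start$init)
  }
  theta0 <- encode_theta(start$params, start$init)
  mask <- if (is.null(opts$mask)) rep(TRUE, 52) else opts$mask
  if (!any(mask)) stop("mask frees no coordinates", call. = FALSE)

  tracker <- new.env(parent = emptyenv())
  tracker$n <- 0L
  tracker$best_theta <- theta0
  tracker$best_val <- Inf

  full_theta <- function(free) {
    th <- theta0
    th[mask] <- free
    th
  }
  fn <- function(free) {
    if (tracker$n >= opts$max_evals) {
      stop(errorCondition("evaluation budget exhausted",
                          class = c("tbinflam_evals_exhausted", "error")))
    }
    tracker$n <- tracker$n + 1L
    th <- full_theta(free)
    v <- fit_objective(th, binned, opts)
    if (v < tracker$best_val) {
      tracker$best_val <- v
      tracker$best_theta <- th
    }
    v
  }

  exhausted <- FALSE
  fn(theta0[mask])  # always evaluate the start
  opt_conv <- 1L
  if (tracker$n < opts$max_evals) {
    res <- tryCatch(
      stats::optim(theta0[mask], fn, method = "Nelder-Mead",
                   control = list(maxit = opts$max_iter,
                                  reltol = opts$tol_f)),
      tbinflam_evals_exhausted = function(e) NULL
    )
    if (is.null(res)) exhausted <- TRUE else opt_conv <- res$convergence
  } else {
    exhausted <- TRUE
  }

  dec <- decode_theta(tracker$best_theta)
  det <- fit_objective(tracker$best_theta, binned, opts, details = TRUE)
  structure(list(
    params = dec$params,
    init = dec$init,
    error = det$error,
    data_term = det$data_term,
    penalty_flags = det$penalty_flags,
    converged = !exhausted && opt_conv == 0L,
    n_evals = tracker$n,
    start = start,
    opts = opts
  ), class = "tbinflam_fit")
}

#' @export
print.tbinflam_fit <- function(x, ...) {
  cat("Model fit: error", format(x$error, digits = 6),
      "(data term", format(x$data_term, digits = 6), ")\n")
  cat("  heuristics violated:",
      if (any(x$penalty_flags, na.rm = TRUE)) {
        paste(names(x$penalty_flags)[which(x$penalty_flags)], collapse = ", ")
      } else "none", "\n")
  cat("  converged:", x$converged, " evaluations:", x$n_evals, "\n")
  invisible(x)
}

#' Serialize a fit to JSON
#'
#' Writes named parameters and initial conditions (not the raw optimizer
#' vector) together with the error decomposition and convergence record.
#'
#' @param fit A `tbinflam_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    params = as.list(fit$params),
    init = as.list(fit$init),
    error = fit$error,
    data_term = fit$data_term,
    penalty_flags = as.list(fit$penalty_flags),
    converged = fit$converged,
    n_evals = fit$n_evals
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
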