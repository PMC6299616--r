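#' Normalized local sensitivity profile for one parameter
#'
#' Central-difference elasticity of the model outputs to one parameter:
#' the model is simulated at `p * (1 - delta)` and `p * (1 + delta)`
#' (default +/- 2 percent) and
#' `S(t) = (x_plus(t) - x_minus(t)) / (2 * delta * p) * p / x_0(t)`,
#' where `x_0` is the unperturbed trajectory. S is dimensionless, so it
#' is invariant to the unit convention of the output. Grid points where
#' `|x_0(t)| < eps_x` are excluded (set `NA`) rather than floored, to
#' avoid manufacturing spurious sensitivities from numerical noise near
#' zero. The scalar summary is the maximum of `|S|` over the requested
#' outputs and included times, and the parameter is flagged when the
#' summary exceeds `threshold`.
#'
#' @param params,init Parameter set and initial state to analyze.
#' @param pname Name of the parameter to perturb.
#' @param outputs State variables to include (default all 7).
#' @param times Evaluation grid in hours (default the 6-h grid over
#'   \[0, 120\]).
#' @param delta Relative perturbation (default 0.02).
#' @param eps_x Near-zero output exclusion threshold (default 1e-8).
#' @param threshold Sensitivity threshold for the flag (default 2).
#' @param rtol,atol Integration tolerances.
#' @return A list of class `tbinflam_sensitivity`: `parameter`, `S`
#'   (time-by-output matrix with a `time_h` attribute), `summary`,
#'   `exceeds_threshold`, `threshold`, `delta`.
#' @export
sensitivity_profile <- function(params, init, pname,
                                outputs = state_names(),
                                times = seq(0, 120, by = 6),
                                delta = 0.02, eps_x = 1e-8, threshold = 2,
                                rtol = 1e-6, atol = 1e-9) {
  params <- validate_params(params)
  init <- validate_state(init)
  if (!pname %in% names(params)) {
    stop("unknown parameter: ", pname, call. = FALSE)
  }
  stopifnot(all(outputs %in% state_names()), delta > 0)
  sim <- function(p) {
    simulate_model(p, init, times = times, rtol = rtol, atol = atol,
                   validate = FALSE)
  }
  base <- sim(params)
  p_lo <- params; p_lo[pname] <- params[pname] * (1 - delta)
  p_hi <- params; p_hi[pname] <- params[pname] * (1 + delta)
  lo <- sim(p_lo)
  hi <- sim(p_hi)
  S <- sapply(outputs, function(st) {
    x0 <- base[[st]]
    s <- (hi[[st]] - lo[[st]]) / (2 * delta * x0)
    s[abs(x0) < eps_x] <- NA_real_
    s
  })
  S <- matrix(S, nrow = length(times), dimnames = list(NULL, outputs))
  attr(S, "time_h") <- times
  smax <- suppressWarnings(max(abs(S), na.rm = TRUE))
  if (!is.finite(smax)) smax <- 0
  structure(list(parameter = pname, S = S, summary = smax,
                 exceeds_threshold = smax > threshold,
                 threshold = threshold, delta = delta),
            class = "tbinflam_sensitivity")
}

#' Sensitivity screen over all 45 parameters
#'
#' Runs [sensitivity_profile()] for every model parameter at a fit's (or
#' an explicitly given) parameter values and initial conditions, and
#' tabulates the scalar summaries against the threshold used to gate the
#' Bhattacharyya comparison.
#'
#' @param fit A `tbinflam_fit`, or a list with `params` and `init`.
#' @param outputs,times,delta,eps_x,threshold,rtol,atol Passed to
#'   [sensitivity_profile()].
#' @return Data frame with columns `parameter`, `summary`,
#'   `exceeds_threshold`, carrying the threshold and delta as
#'   attributes.
#' @export
sensitivity_screen <- function(fit, outputs = state_names(),
                               times = seq(0, 120, by = 6), delta = 0.02,
                               eps_x = 1e-8, threshold = 2,
                               rtol = 1e-6, atol = 1e-9) {
  params <- validate_params(fit$params)
  init <- validate_state(fit$init)
  rows <- lapply(param_names(), function(pn) {
    pr <- sensitivity_profile(params, init, pn, outputs = outputs,
                              times = times, delta = delta, eps_x = eps_x,
                              threshold = threshold, rtol = rtol, atol = atol)
    data.frame(parameter = pn, summary = pr$summary,
               exceeds_threshold = pr$exceeds_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "delta") <- delta
  out
}

#' Write sensitivity outputs to CSV
#'
#' `write_sensitivity_csv()` writes the long per-time table (`parameter`,
#' `output`, `time_h`, `S`) for one profile;
#' `write_sensitivity_summary_csv()` writes the screen summary table.
#'
#' @param profile A `tbinflam_sensitivity`.
#' @param screen Output of [sensitivity_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(profile, path) {
  times <- attr(profile$S, "time_h")
  long <- do.call(rbind, lapply(colnames(profile$S), function(st) {
    data.frame(parameter = profile$parameter, output = st,
               time_h = times, S = profile$S[, st])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensitivity_csv
#' @export
write_sensitivity_summary_csv <- function(screen, path) {
  utils::write.csv(screen, path, row.names = FALSE)
  invisible(path)
}
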