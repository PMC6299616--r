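#' Perturb a baseline parameter set and initial state
#'
#' Multiplies each of the 45 parameters and (by default) the 7 initial
#' conditions by an independent uniform draw on \[0.5, 1.5\] of the
#' baseline value, re-applying the Hill-exponent floor of 1. This is the
#' restart law used to build fit ensembles.
#'
#' @param params,init Baseline parameter set and initial state.
#' @param multipliers Optional 52-vector of multipliers (parameters then
#'   initial conditions) overriding the random draw; used for
#'   deterministic checks.
#' @param perturb_init If `FALSE`, initial conditions are left at
#'   baseline.
#' @return List with perturbed `params` and `init`.
#' @export
perturb_start <- function(params, init, multipliers = NULL,
                          perturb_init = TRUE) {
  params <- validate_params(params)
  init <- validate_state(init)
  if (is.null(multipliers)) {
    multipliers <- stats::runif(52, 0.5, 1.5)
  }
  stopifnot(length(multipliers) == 52, all(is.finite(multipliers)))
  p <- params * multipliers[1:45]
  he <- hill_exponent_names()
  p[he] <- pmax(p[he], 1)
  s <- if (perturb_init) init * multipliers[46:52] else init
  list(params = p, init = s)
}

#' Build an ensemble of perturbed refits
#'
#' Draws `n` perturbed restarts of the baseline fit (multiplicative
#' U(0.5, 1.5) on every optimized quantity), refits each against the same
#' binned data, and collects the results. A master seed spawns one
#' substream seed per member, so the ensemble is reproducible and
#' independent of execution order. A member whose perturbed start fails
#' to integrate (sentinel objective) is redrawn once from its substream
#' before being kept as a sentinel-error member.
#'
#' @param baseline A `tbinflam_fit` obtained on `binned`.
#' @param binned Binned series the baseline was fitted to.
#' @param n Number of members (default 100).
#' @param seed Master seed (integer).
#' @param opts Fitting options for the refits (default: the baseline's).
#' @param perturb_init Perturb initial conditions alongside parameters
#'   (default `TRUE`).
#' @param cluster Optional cluster label stored on the ensemble.
#' @return A list of class `tbinflam_ensemble`: `cluster`, `members`
#'   (list of `tbinflam_fit`), `baseline`, `seed`, `n_retries`.
#' @export
build_ensemble <- function(baseline, binned, n = 100, seed = 1,
                           opts = NULL, perturb_init = TRUE,
                           cluster = NULL) {
  stopifnot(inherits(baseline, "tbinflam_fit"), n >= 1)
  if (is.null(opts)) opts <- baseline$opts
  set.seed(seed)
  member_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_retries <- 0L
  members <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(member_seeds[i])
    start <- perturb_start(baseline$params, baseline$init,
                           perturb_init = perturb_init)
    th <- encode_theta(start$params, start$init)
    if (fit_objective(th, binned, opts) >= opts$sentinel) {
      n_retries <- n_retries + 1L
      start <- perturb_start(baseline$params, baseline$init,
                             perturb_init = perturb_init)
    }
    fit <- fit_model(start, binned, opts)
    fit$member_seed <- member_seeds[i]
    members[[i]] <- fit
  }
  if (n_retries > 0) {
    message(n_retries, " member start(s) failed to integrate and were redrawn")
  }
  structure(list(cluster = cluster, members = members, baseline = baseline,
                 seed = seed, n_retries = n_retries),
            class = "tbinflam_ensemble")
}

#' @export
print.tbinflam_ensemble <- function(x, ...) {
  errs <- vapply(x$members, function(m) m$error, numeric(1))
  cat("Ensemble", if (!is.null(x$cluster)) paste0("(", x$cluster, ")"),
      "of", length(x$members), "fits; error min/median/max:",
      paste(format(stats::quantile(errs, c(0, 0.5, 1)), digits = 4),
            collapse = " / "), "\n")
  invisible(x)
}

#' Flatten an ensemble to a wide data frame
#'
#' One row per member: `member`, `error`, `data_term`, `converged`, the
#' 45 parameter columns, and the 7 initial-condition columns prefixed
#' `init_`. This wide table is the input contract for
#' [compare_ensembles()] CSV round trips.
#'
#' @param x A `tbinflam_ensemble`.
#' @param ... Unused.
#' @return Data frame with `nrow = ` number of members.
#' @export
as.data.frame.tbinflam_ensemble <- function(x, ...) {
  rows <- lapply(seq_along(x$members), function(i) {
    m <- x$members[[i]]
    data.frame(member = i, error = m$error, data_term = m$data_term,
               converged = m$converged,
               as.list(m$params),
               stats::setNames(as.list(m$init),
                               paste0("init_", names(m$init))),
               check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read an ensemble as CSV + JSON manifest
#'
#' Writes the wide member table to `path` and, alongside it, a
#' `<path>.manifest.json` with the cluster label, seed, retry count and
#' baseline solution (full provenance).
#'
#' @param ensemble A `tbinflam_ensemble`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(as.data.frame(ensemble), path, row.names = FALSE)
  jsonlite::write_json(list(
    cluster = ensemble$cluster,
    seed = ensemble$seed,
    n_members = length(ensemble$members),
    n_retries = ensemble$n_retries,
    baseline = list(params = as.list(ensemble$baseline$params),
                    init = as.list(ensemble$baseline$init),
                    error = ensemble$baseline$error)
  ), paste0(path, ".manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Per-parameter distribution summary of an ensemble
#'
#' @param ensemble A `tbinflam_ensemble` or its wide data frame.
#' @return Data frame with one row per parameter and initial condition:
#'   `name`, `mean`, `sd`, `q25`, `median`, `q75`, `min`, `max`.
#' @export
ensemble_summary <- function(ensemble) {
  df <- if (is.data.frame(ensemble)) ensemble else as.data.frame(ensemble)
  if (!nrow(df)) stop("empty ensemble", call. = FALSE)
  cols <- c(param_names(), paste0("init_", state_names()))
  cols <- intersect(cols, names(df))
  rows <- lapply(cols, function(cn) {
    v <- df[[cn]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(name = cn, mean = mean(v), sd = stats::sd(v),
               q25 = q[1], median = q[2], q75 = q[3],
               min = min(v), max = max(v))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
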