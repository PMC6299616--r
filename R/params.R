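#' Names of the 45 biological model parameters
#'
#' The parameter vector of the neuroinflammation ODE model, grouped as:
#' resting microglia source/decay (`s_mr`, `mu_mr`); M1-like activation
#' (`k_n1`, `k_n12`, `b_n`, `x_n`, `a_inf1`); M2-like activation (`k_n4`,
#' `k_n10`, `y_n`, `z_n`); the M1-to-M2 phenotype switch (`tau_n4`,
#' `tau_n10`, `m_n`, `g_n`); microglial decay (`mu_M1`, `mu_M2`); cytokine
#' release by Th2 cells (`k_tbase`, `k_tn12`, `r_n`, `c_n`);
#' pro-inflammatory production and decay (`k_M1base`, `kcd`, `v_n`, `h_n`,
#' `k_pn1`, `k_pn12`, `mu_n1`, `mu_n12`); anti-inflammatory production and
#' decay (`k_M2base`, `kc4`, `w_n`, `q_n`, `a_inf2`, `k_tn10`, `k_tn4`,
#' `k_pn10`, `k_pn4`, `mu_n10`, `mu_n4`); and secondary tissue damage
#' (`alpha_n12`, `alpha_n1`, `gamma_M1`, `gamma_M2`, `r_M1`).
#'
#' Rates are per hour; half-activation constants share the pg/mL scale of
#' the cytokine states; `x_n`, `z_n`, `g_n`, `c_n`, `h_n` and `q_n` are
#' dimensionless Hill exponents constrained to be >= 1.
#'
#' @return Character vector of length 45.
#' @export
param_names <- function() {
  c(
    "s_mr", "mu_mr",
    "k_n1", "k_n12", "b_n", "x_n", "a_inf1",
    "k_n4", "k_n10", "y_n", "z_n",
    "tau_n4", "tau_n10", "m_n", "g_n",
    "mu_M1", "mu_M2",
    "k_tbase", "k_tn12", "r_n", "c_n",
    "k_M1base", "kcd", "v_n", "h_n", "k_pn1", "k_pn12", "mu_n1", "mu_n12",
    "k_M2base", "kc4", "w_n", "q_n", "a_inf2",
    "k_tn10", "k_tn4", "k_pn10", "k_pn4", "mu_n10", "mu_n4",
    "alpha_n12", "alpha_n1", "gamma_M1", "gamma_M2", "r_M1"
  )
}

#' Names of the Hill-exponent parameters
#'
#' The six Hill exponents of the model, each constrained to be >= 1.
#'
#' @return Character vector of length 6.
#' @export
hill_exponent_names <- function() {
  c("x_n", "z_n", "g_n", "c_n", "h_n", "q_n")
}

#' Names of the 7 model state variables
#'
#' `M1`, `M2`: M1-/M2-like microglia (arbitrary units); `IL1`, `IL12`,
#' `IL10`, `IL4`: cytokine concentrations (pg/mL scale); `D`: qualitative
#' secondary tissue damage (arbitrary units).
#'
#' @return Character vector of length 7.
#' @export
state_names <- function() {
  c("M1", "M2", "IL1", "IL12", "IL10", "IL4", "D")
}

#' The four modeled CSF analytes
#'
#' Analyte labels used in cytokine tables, in the order matching the
#' corresponding model states `IL1`, `IL12`, `IL10`, `IL4`.
#'
#' @return Named character vector mapping analyte label to state name.
#' @export
analyte_states <- function() {
  c(IL1b = "IL1", IL12 = "IL12", IL10 = "IL10", IL4 = "IL4")
}

#' Validate a model parameter set
#'
#' Checks that `params` is a full named numeric vector over
#' [param_names()], strictly positive, finite, with Hill exponents >= 1.
#' Extra names are rejected; order is normalized to [param_names()].
#'
#' @param params Named numeric vector of the 45 model parameters.
#' @return The validated parameter vector, reordered canonically.
#' @export
validate_params <- function(params) {
  nm <- param_names()
  if (is.list(params)) params <- unlist(params)
  if (!is.numeric(params) || is.null(names(params))) {
    stop("`params` must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(nm, names(params))
  extra <- setdiff(names(params), nm)
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(extra)) {
    stop("unknown parameters: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  params <- params[nm]
  if (any(!is.finite(params))) {
    stop("non-finite parameter values: ",
         paste(nm[!is.finite(params)], collapse = ", "), call. = FALSE)
  }
  if (any(params <= 0)) {
    stop("parameters must be strictly positive: ",
         paste(nm[params <= 0], collapse = ", "), call. = FALSE)
  }
  he <- hill_exponent_names()
  if (any(params[he] < 1)) {
    stop("Hill exponents must be >= 1: ",
         paste(he[params[he] < 1], collapse = ", "), call. = FALSE)
  }
  params
}

#' Validate a model state
#'
#' Checks that `state` is a full named numeric vector over
#' [state_names()] with finite, nonnegative entries.
#'
#' @param state Named numeric vector of the 7 state variables.
#' @return The validated state vector, reordered canonically.
#' @export
validate_state <- function(state) {
  nm <- state_names()
  if (is.list(state)) state <- unlist(state)
  if (!is.numeric(state) || is.null(names(state))) {
    stop("`state` must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(nm, names(state))
  extra <- setdiff(names(state), nm)
  if (length(missing)) {
    stop("missing state variables: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra)) {
    stop("unknown state variables: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  state <- state[nm]
  if (any(!is.finite(state))) {
    stop("non-finite state values", call. = FALSE)
  }
  if (any(state < 0)) {
    stop("state variables must be nonnegative: ",
         paste(nm[state < 0], collapse = ", "), call. = FALSE)
  }
  state
}

#' Read / write parameter sets and initial conditions
#'
#' Parameter sets and initial states are serialized as flat JSON or YAML
#' maps keyed by the parameter symbol names (ASCII transliteration, e.g.
#' `a_inf1`). Format is chosen by file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param x Named numeric vector (a parameter set or a state).
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_param_map()` returns `path` invisibly;
#'   `read_param_map()` returns a named numeric vector.
#' @export
write_param_map <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(as.list(x), path)
  } else {
    stop("unsupported extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_param_map
#' @export
read_param_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unsupported extension: ", ext, call. = FALSE)
  }
  unlist(x)
}
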