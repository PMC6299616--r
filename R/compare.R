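#' Histogram Bhattacharyya coefficient and distance
#'
#' Bins both samples on shared equal-width edges spanning the pooled
#' range, converts counts to proportions `p`, `q`, and returns the
#' overlap coefficient `bc = sum(sqrt(p * q))` together with the distance
#' `bd = -log(bc)`. `bc = 1` indicates identical histograms, `bc = 0`
#' non-overlapping support, in which case `bd` is undefined and returned
#' as `NA`. When all pooled values coincide, both samples occupy the
#' single degenerate bin and `bc = 1`.
#'
#' @param sample_a,sample_b Numeric samples, each of length >= 2.
#' @param bins A single bin count (default 10) or an explicit vector of
#'   shared bin edges covering both samples.
#' @return List with components `bc` (in \[0, 1\]) and `bd` (positive or
#'   `NA` when `bc = 0`).
#' @export
bhattacharyya <- function(sample_a, sample_b, bins = 10) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample must have at least 2 values", call. = FALSE)
  }
  if (any(!is.finite(sample_a)) || any(!is.finite(sample_b))) {
    stop("samples must be finite", call. = FALSE)
  }
  if (length(bins) == 1) {
    stopifnot(bins >= 1)
    lo <- min(sample_a, sample_b)
    hi <- max(sample_a, sample_b)
    if (hi == lo) {
      return(list(bc = 1, bd = 0))
    }
    edges <- seq(lo, hi, length.out = bins + 1)
  } else {
    edges <- sort(bins)
    if (min(sample_a, sample_b) < edges[1] ||
        max(sample_a, sample_b) > edges[length(edges)]) {
      stop("explicit edges must span both samples", call. = FALSE)
    }
  }
  count_in <- function(x) {
    # rightmost bin closed so the pooled maximum is counted
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(idx, nbins = length(edges) - 1)
  }
  p <- count_in(sample_a) / length(sample_a)
  q <- count_in(sample_b) / length(sample_b)
  bc <- min(max(sum(sqrt(p * q)), 0), 1)
  list(bc = bc, bd = if (bc > 0) -log(bc) else NA_real_)
}

#' Gaussian closed-form Bhattacharyya metrics
#'
#' Treats each sample as Gaussian with its empirical mean and variance:
#' `bd = 1/4 * log(1/4 * (sa2/sb2 + sb2/sa2 + 2)) +
#' 1/4 * (ma - mb)^2 / (sa2 + sb2)` and `bc = exp(-bd)`. Provided as a
#' parametric cross-check of the default histogram overlap; never zero,
#' so it cannot reproduce the empirical non-overlap case.
#'
#' @param sample_a,sample_b Numeric samples of length >= 2 with nonzero
#'   variance.
#' @return List with components `bc` and `bd`.
#' @export
gaussian_bhattacharyya <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample must have at least 2 values", call. = FALSE)
  }
  va <- stats::var(sample_a)
  vb <- stats::var(sample_b)
  if (va == 0 || vb == 0) stop("zero variance sample", call. = FALSE)
  ma <- mean(sample_a)
  mb <- mean(sample_b)
  bd <- 0.25 * log(0.25 * (va / vb + vb / va + 2)) +
    0.25 * (ma - mb)^2 / (va + vb)
  list(bc = exp(-bd), bd = bd)
}

#' Compare per-parameter distributions of two ensembles
#'
#' Computes histogram Bhattacharyya overlap (BC) and distance (BD)
#' between the two ensembles' member values of every parameter, ranks
#' parameters by ascending BC with ties broken by descending BD
#' (undefined BD, i.e. BC = 0, sorts first), and applies the selection
#' rule: a parameter's distributions are called disparate when
#' `BC <= bc_max` and `BD >= bd_min` (undefined BD passes the BD bound)
#' and, if sensitivity summaries are supplied, the parameter's model
#' sensitivity exceeds the threshold in at least one cluster's baseline
#' fit. Initial-condition columns are excluded by default.
#'
#' @param e_a,e_b `tbinflam_ensemble` objects or wide ensemble data
#'   frames (see [as.data.frame.tbinflam_ensemble()]) over the same
#'   parameter names.
#' @param sens_a,sens_b Optional sensitivity screens (data frames with
#'   columns `parameter`, `summary`, `exceeds_threshold`, from
#'   [sensitivity_screen()]) for the two clusters' baselines. When
#'   omitted, `passes_sensitivity` is `NA` and `disparate` uses the
#'   Bhattacharyya rule alone.
#' @param bc_max,bd_min Selection thresholds (defaults 0.38 and 0.97).
#' @param bins Histogram bin setting passed to [bhattacharyya()].
#' @param include_init Also compare initial-condition columns (default
#'   `FALSE`).
#' @return Data frame of class `tbinflam_comparison`, ordered by rank,
#'   with columns `parameter`, `bc`, `bd`, `passes_bhatt`,
#'   `passes_sensitivity`, `disparate`, `rank`.
#' @export
compare_ensembles <- function(e_a, e_b, sens_a = NULL, sens_b = NULL,
                              bc_max = 0.38, bd_min = 0.97, bins = 10,
                              include_init = FALSE) {
  df_a <- if (is.data.frame(e_a)) e_a else as.data.frame(e_a)
  df_b <- if (is.data.frame(e_b)) e_b else as.data.frame(e_b)
  cols <- param_names()
  if (include_init) cols <- c(cols, paste0("init_", state_names()))
  miss_a <- setdiff(cols, names(df_a))
  miss_b <- setdiff(cols, names(df_b))
  if (length(miss_a) || length(miss_b)) {
    stop("ensembles lack parameter columns: ",
         paste(unique(c(miss_a, miss_b)), collapse = ", "), call. = FALSE)
  }
  sens_lookup <- function(sens, pn) {
    if (is.null(sens)) return(NA_real_)
    i <- match(pn, sens$parameter)
    if (is.na(i)) NA_real_ else sens$summary[i]
  }
  threshold <- attr(sens_a, "threshold")
  if (is.null(threshold)) threshold <- attr(sens_b, "threshold")
  if (is.null(threshold)) threshold <- 2

  rows <- lapply(cols, function(pn) {
    m <- bhattacharyya(df_a[[pn]], df_b[[pn]], bins = bins)
    s <- c(sens_lookup(sens_a, pn), sens_lookup(sens_b, pn))
    ps <- if (all(is.na(s))) NA else any(s > threshold, na.rm = TRUE)
    pb <- m$bc <= bc_max && (is.na(m$bd) || m$bd >= bd_min)
    data.frame(parameter = pn, bc = m$bc, bd = m$bd,
               passes_bhatt = pb, passes_sensitivity = ps,
               disparate = pb && (is.na(ps) || ps))
  })
  out <- do.call(rbind, rows)
  bd_sort <- ifelse(is.na(out$bd), Inf, out$bd)
  ord <- order(out$bc, -bd_sort)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("tbinflam_comparison", class(out))
  out
}

#' Write a comparison table to CSV
#'
#' Undefined BD (BC = 0) serializes as `"n/a"`, mirroring how
#' non-overlapping distributions are reported.
#'
#' @param comparison Output of [compare_ensembles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  df <- as.data.frame(comparison)
  df$bd <- ifelse(is.na(df$bd), "n/a", format(df$bd, digits = 10))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
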