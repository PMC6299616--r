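#' Read a longitudinal CSF cytokine table
#'
#' Reads a CSV with columns `patient_id`, `cluster`, `time_h`, `analyte`,
#' `concentration_pg_ml`: one row per measured analyte per CSF draw,
#' times in hours post-injury within \[0, 120\], concentrations in pg/mL.
#' Rows whose analyte is not one of the four modeled cytokines
#' (`IL1b`, `IL4`, `IL10`, `IL12`) are dropped with a message giving the
#' dropped count. Returns one series per patient, in first-appearance
#' order.
#'
#' @param path CSV file path.
#' @return A list of per-patient data frames (columns `time_h`,
#'   `analyte`, `concentration_pg_ml`), each carrying attributes
#'   `patient_id` and `cluster`; the list itself has class
#'   `cytokine_series_list`.
#' @export
read_cytokine_table <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  required <- c("patient_id", "cluster", "time_h", "analyte",
                "concentration_pg_ml")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df$time_h <- suppressWarnings(as.numeric(df$time_h))
  df$concentration_pg_ml <- suppressWarnings(as.numeric(df$concentration_pg_ml))
  bad <- which(!is.finite(df$time_h) | !is.finite(df$concentration_pg_ml))
  if (length(bad)) {
    stop("unparsable numeric value at row ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  bad <- which(df$concentration_pg_ml < 0)
  if (length(bad)) {
    stop("negative concentration at row ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  bad <- which(df$time_h < 0 | df$time_h > 120)
  if (length(bad)) {
    stop("time outside [0, 120] h at row ", bad[1] + 1L, " of ", path,
         call. = FALSE)
  }
  known <- df$analyte %in% names(analyte_states())
  if (any(!known)) {
    message("dropping ", sum(!known), " rows with unmodeled analytes: ",
            paste(unique(df$analyte[!known]), collapse = ", "))
    df <- df[known, , drop = FALSE]
  }
  as_series_list(df)
}

#' Split a tidy cytokine table into per-patient series
#'
#' @param df Data frame with the [read_cytokine_table()] columns.
#' @return A `cytokine_series_list` (see [read_cytokine_table()]).
#' @export
as_series_list <- function(df) {
  ids <- unique(df$patient_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$patient_id == id,
               c("time_h", "analyte", "concentration_pg_ml")]
    rownames(rows) <- NULL
    cl <- unique(df$cluster[df$patient_id == id])
    if (length(cl) != 1) {
      stop("patient ", id, " has multiple cluster labels", call. = FALSE)
    }
    attr(rows, "patient_id") <- as.character(id)
    attr(rows, "cluster") <- as.character(cl)
    rows
  })
  names(out) <- as.character(ids)
  class(out) <- c("cytokine_series_list", class(out))
  out
}

#' Moving-average bin centers
#'
#' Centers of the 19 overlapping 12-h windows shifted by 6 h (0-12,
#' 6-18, ..., 108-120 h), i.e. 6, 12, ..., 114 h.
#'
#' @return Numeric vector of length 19.
#' @export
bin_centers <- function() 6 * (1:19)

#' Moving-average binning of cytokine series
#'
#' Pools all measurements of one cluster's patients into overlapping 12-h
#' windows shifted by 6 h (0-12, 6-18, ..., 108-120 h post-injury) and
#' summarizes each window per analyte: mean, sample standard deviation,
#' standard error `sd/sqrt(n)` and count. Windows are half-open
#' `[lo, hi)` except the last, which closes at 120 h, so a measurement at
#' an interior 6-h mark contributes to exactly two windows and no
#' measurement is counted three times. Empty windows are reported with
#' `n = 0` and `NA` summaries (never interpolated); windows with a single
#' value carry its mean but `NA` sd/se.
#'
#' @param group A `cytokine_series_list`, a single per-patient series, or
#'   a tidy data frame with columns `time_h`, `analyte`,
#'   `concentration_pg_ml` (and optionally `cluster`). All series must
#'   come from one cluster.
#' @return Data frame with columns `analyte`, `bin_center_h`, `mean`,
#'   `sd`, `se`, `n`, ordered by analyte then bin center; attribute
#'   `cluster` when known.
#' @export
bin_series <- function(group) {
  if (inherits(group, "cytokine_series_list") ||
      (is.list(group) && !is.data.frame(group))) {
    if (!length(group)) stop("empty series group", call. = FALSE)
    clusters <- unique(vapply(group, function(s) {
      cl <- attr(s, "cluster")
      if (is.null(cl)) NA_character_ else as.character(cl)
    }, character(1)))
    clusters <- clusters[!is.na(clusters)]
    if (length(clusters) > 1) {
      stop("mixed-cluster input: ", paste(clusters, collapse = ", "),
           call. = FALSE)
    }
    df <- do.call(rbind, lapply(group, function(s) {
      s[, c("time_h", "analyte", "concentration_pg_ml")]
    }))
  } else {
    df <- group
    clusters <- unique(df$cluster)
    if (length(clusters) > 1) {
      stop("mixed-cluster input: ", paste(clusters, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!nrow(df)) stop("no measurements to bin", call. = FALSE)
  centers <- bin_centers()
  analytes <- names(analyte_states())
  res <- expand.grid(bin_center_h = centers, analyte = analytes,
                     stringsAsFactors = FALSE)[, 2:1]
  stats <- mapply(function(an, ctr) {
    lo <- ctr - 6
    hi <- ctr + 6
    inwin <- df$analyte == an & df$time_h >= lo &
      (if (hi >= 120) df$time_h <= 120 else df$time_h < hi)
    v <- df$concentration_pg_ml[inwin]
    n <- length(v)
    c(mean = if (n) mean(v) else NA_real_,
      sd = if (n >= 2) stats::sd(v) else NA_real_,
      n = n)
  }, res$analyte, res$bin_center_h)
  res$mean <- stats["mean", ]
  res$sd <- stats["sd", ]
  res$se <- res$sd / sqrt(stats["n", ])
  res$n <- as.integer(stats["n", ])
  rownames(res) <- NULL
  if (length(clusters) == 1) attr(res, "cluster") <- as.character(clusters)
  res
}

#' Write / read a binned series table
#'
#' CSV with columns `analyte`, `bin_center_h`, `mean`, `sd`, `se`, `n`.
#'
#' @param binned Output of [bin_series()].
#' @param path File path.
#' @return `path` invisibly / the binned data frame.
#' @export
write_binned_csv <- function(binned, path) {
  utils::write.csv(binned, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binned_csv
#' @export
read_binned_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a cohort table in the cytokine-table dialect
#'
#' @param table Tidy data frame with the [read_cytokine_table()] columns.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cytokine_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
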