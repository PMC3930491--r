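#' Write a flow field (or list of frames) to CSV
#'
#' One row per visible dot per frame with columns
#' `frame, x_img, y_img, u, v`.
#'
#' @param flows An `mst_flow` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(flows, path) {
  if (inherits(flows, "mst_flow")) flows <- list(flows)
  df <- do.call(rbind, lapply(flows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a flow CSV written by [write_flow_csv()]
#'
#' @param path Input path.
#' @return A data frame with columns `frame, x_img, y_img, u, v`.
#' @export
read_flow_csv <- function(path) {
  utils::read.csv(path)
}

#' Write an experiment report
#'
#' `"csv"` writes the raw trial table (header-only if the report is
#' empty); `"json"` writes the trial table together with the aggregate
#' summary.
#'
#' @param report An `mst_report` (or any list with `trials` and optionally
#'   `summary` data frames).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  trials <- report$trials
  if (is.null(trials)) stop("report has no `trials` table", call. = FALSE)
  if (format == "csv") {
    utils::write.csv(trials, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(trials = trials, summary = report$summary),
      path, dataframe = "rows", digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"json"`.
#' @return For `"csv"`, the trial data frame; for `"json"`, a list with
#'   `trials` and `summary`.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path)
  else jsonlite::fromJSON(path)
}

#' Write an activity dump
#'
#' One row per unit per frame: unit id, pattern angle, spirality,
#' orientation, CoM offsets, frame, activation.
#'
#' @param activity An `mst_activity` from [run_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  u <- activity$bank$units
  n <- nrow(u)
  frames <- ncol(activity$z)
  df <- data.frame(
    unit = rep(seq_len(n), times = frames),
    phi = rep(u$phi, times = frames),
    spirality = rep(u$spirality, times = frames),
    orientation = rep(u$orientation, times = frames),
    cx = rep(u$cx, times = frames),
    cy = rep(u$cy, times = frames),
    frame = rep(seq_len(frames), each = n),
    z = as.vector(activity$z)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
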