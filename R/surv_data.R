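#' Individual patient data container
#'
#' A validated data frame of one record per subject: a positive
#' time-to-event `time` (months) and an `event` indicator (1 = event
#' observed, 0 = censored). An optional `arm` column labels treatment arms.
#'
#' @param time Numeric vector of positive times (months).
#' @param event Vector of 0/1 event indicators, same length as `time`.
#' @param arm Optional vector of arm labels.
#' @return A data frame of class `"surv_data"`.
#' @seealso [read_ipd()], [km_estimate()]
#' @export
surv_data <- function(time, event, arm = NULL) {
  df <- data.frame(time = as.numeric(time), event = as.numeric(event))
  if (!is.null(arm)) df$arm <- arm
  validate_surv_data(df)
}

validate_surv_data <- function(df, where = NULL) {
  tag <- if (is.null(where)) "" else paste0(" in ", where)
  if (!all(c("time", "event") %in% names(df)))
    stop("missing required columns 'time' and/or 'event'", tag)
  bad_time <- which(!is.finite(df$time) | df$time <= 0)
  if (length(bad_time))
    stop("times must be positive and finite; offending row(s)", tag, ": ",
         paste(utils::head(bad_time, 10), collapse = ", "))
  bad_event <- which(!(df$event %in% c(0, 1)))
  if (length(bad_event))
    stop("event indicators must be 0 or 1; offending row(s)", tag, ": ",
         paste(utils::head(bad_event, 10), collapse = ", "))
  class(df) <- c("surv_data", "data.frame")
  df
}

is_surv_data <- function(x) inherits(x, "surv_data")

#' @export
print.surv_data <- function(x, ...) {
  cat(sprintf("Survival data: %d subjects, %d events (%.1f%% censored)\n",
              nrow(x), sum(x$event),
              100 * mean(x$event == 0)))
  if ("arm" %in% names(x)) {
    tab <- table(x$arm)
    cat("Arms:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read individual patient data from delimited text
#'
#' Expects a header with columns `time` and `event` (and optionally `arm`).
#' Rows violating the container invariants are reported by row number.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return A [surv_data()] object.
#' @export
read_ipd <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("time", "event") %in% names(df)))
    stop("file ", path, " lacks required columns 'time' and 'event'")
  if (!is.numeric(df$time))
    stop("column 'time' in ", path, " is not numeric")
  validate_surv_data(df, where = path)
}

#' Write individual patient data to delimited text
#'
#' @param data A [surv_data()] object.
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_ipd <- function(data, path, sep = ",") {
  stopifnot(is_surv_data(data))
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
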