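`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half-up
#'
#' Rounding used for reported values (percentages, adjusted limits). Plain
#' `round()` rounds half to even; clinical reports conventionally round half
#' away from zero, so 82.715 prints as 82.72.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Parse timestamps into UTC POSIXct
#'
#' Accepts POSIXct as-is; character timestamps are parsed as
#' `"YYYY-MM-DD HH:MM:SS"` (or ISO-8601 with a `T` separator) in UTC.
#' Timestamp arithmetic throughout the package is done on these values,
#' with a day taken as exactly 86400 seconds.
#'
#' @param x POSIXct or character vector.
#' @return POSIXct vector in UTC.
#' @export
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC")
  if (anyNA(out) && !anyNA(x)) {
    stop("unparseable timestamp(s): ", paste(utils::head(x[is.na(out)], 3), collapse = ", "),
         call. = FALSE)
  }
  out
}

# difference now - then in fractional hours / days
hours_between <- function(then, now) as.numeric(difftime(now, then, units = "secs")) / 3600
days_between <- function(then, now) as.numeric(difftime(now, then, units = "secs")) / 86400

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_config <- function(..., path = NULL) {
  msg <- paste0(...)
  if (!is.null(path)) msg <- paste0(path, ": ", msg)
  cond <- structure(
    class = c("coag_config_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

stop_input <- function(...) {
  cond <- structure(
    class = c("coag_input_error", "error", "condition"),
    list(message = paste0(...), call = NULL)
  )
  stop(cond)
}
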