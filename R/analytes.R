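#' Coagulation panel analytes
#'
#' The four core assays of a routine coagulation panel. `PT`, `APTT` and `TT`
#' are clot-formation times in seconds; `FBG` is the fibrinogen concentration
#' in g/L. The derived `INR` (a standardized PT ratio, dimensionless) is
#' accepted as an optional fifth result and is only consulted under
#' anticoagulant-therapy contexts.
#'
#' @return character vector of the four core analyte codes.
#' @export
analytes <- function() c("PT", "APTT", "TT", "FBG")

# all codes accepted in result tables
ALL_CODES <- c("PT", "APTT", "TT", "FBG", "INR")

#' @rdname analytes
#' @param code analyte code.
#' @return `analyte_unit()`: the reporting unit for a code.
#' @export
analyte_unit <- function(code) {
  check_analyte(code, allow_inr = TRUE)
  c(PT = "s", APTT = "s", TT = "s", FBG = "g/L", INR = "ratio")[[code]]
}

check_analyte <- function(code, allow_inr = FALSE) {
  ok <- if (allow_inr) ALL_CODES else analytes()
  if (!(is.character(code) && length(code) == 1L && code %in% ok)) {
    stop_input("unknown analyte code: ", paste(code, collapse = ","),
               " (accepted: ", paste(ok, collapse = ", "), ")")
  }
  invisible(code)
}
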