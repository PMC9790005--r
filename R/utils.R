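# internal helpers shared across modules

#' @keywords internal
#' @noRd
detect_delim <- function(path) {
  con <- file(path, "rt")
  on.exit(close(con))
  line1 <- readLines(con, n = 1L)
  if (length(line1) == 0L) stop("file is empty: ", path, call. = FALSE)
  if (grepl("\t", line1, fixed = TRUE)) "\t" else ","
}

# round half away from zero, the convention of the printed tables
#' Round half away from zero
#'
#' Rounding used for table display: halves move away from zero (so 0.125
#' prints as 0.13 and -0.125 as -0.13), unlike [base::round()]'s banker's
#' rounding. Full precision is always retained internally; this is applied
#' only when formatting.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 2) {
  s <- 10^digits
  # nudge by eps so that values stored as e.g. 0.1249999999999 from decimal
  # arithmetic still round the way their exact decimal value would
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' @keywords internal
#' @noRd
stop_format <- function(...) {
  stop(structure(class = c("drmage_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
#' @noRd
stop_validation <- function(...) {
  stop(structure(class = c("drmage_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
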