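# Social class coding: three ordered NS-SEC-derived categories.

#' Social class levels
#'
#' The three collapsed NS-SEC occupational categories used throughout,
#' ordered from lowest to highest rank.
#'
#' @return character vector `c("disadvantaged", "intermediate", "advantaged")`.
#' @export
class_levels <- function() c("disadvantaged", "intermediate", "advantaged")

#' Coerce to an ordered social class code
#'
#' Accepts character labels, factors, or integer ranks 1..3 (1 =
#' disadvantaged, 3 = advantaged) and returns an ordered factor with the
#' fixed three-level vocabulary. Unrecognized values become `NA`.
#'
#' @param x vector of class labels or ranks.
#' @return ordered factor with levels [class_levels()].
#' @export
class_code <- function(x) {
  lv <- class_levels()
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% 1:3)
    if (any(bad)) stop_validation("class ranks must be in 1..3")
    return(factor(lv[x], levels = lv, ordered = TRUE))
  }
  x <- as.character(x)
  known <- is.na(x) | x %in% lv
  if (!all(known)) {
    stop_validation("unknown class labels: ",
                    paste(unique(x[!known]), collapse = ", "))
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' Dominance (highest-class) rule for a household
#'
#' Returns the most advantaged class among the available household members,
#' the rule used to assign both childhood class (highest of the parents) and
#' adult class (most advantaged person in the household). A single available
#' member's class is used as-is; if every member is missing, `NA` is
#' returned.
#'
#' @param member_classes vector coercible by [class_code()]; one element per
#'   household member, `NA` allowed.
#' @return length-1 ordered factor (possibly `NA`).
#' @export
#' @examples
#' household_max_class(c("intermediate", "advantaged"))  # advantaged
household_max_class <- function(member_classes) {
  cc <- class_code(member_classes)
  cc <- cc[!is.na(cc)]
  if (length(cc) == 0L) {
    return(factor(NA_character_, levels = class_levels(), ordered = TRUE))
  }
  cc[which.max(as.integer(cc))]
}
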