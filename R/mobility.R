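# Analytic-sample construction and social-mobility encoding.
#
# Origin class is the (household-maximum) class at age 14; destination class
# is the adult household class. Mobility is any difference between the two,
# with direction and step count derived from the fixed class ranks.

#' Filter to the analytic sample
#'
#' Retains rows with age at or above `min_age` (participants below 25 are
#' excluded by default as unlikely to have reached occupational maturity)
#' and non-missing origin, destination, sex and age. Counts removed for each
#' reason are logged via `message()` and attached as attribute
#' `"exclusions"`.
#'
#' @param cohort data frame with columns `age`, `sex`, `origin`,
#'   `destination` (plus anything else, carried through).
#' @param min_age minimum age retained (inclusive).
#' @return the filtered data frame; errors if no rows survive.
#' @export
filter_analytic_sample <- function(cohort, min_age = 25) {
  need <- c("age", "sex", "origin", "destination")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop_validation("cohort lacks columns: ", paste(miss, collapse = ", "))
  n0 <- nrow(cohort)
  drops <- c(missing_age = 0L, under_min_age = 0L, missing_origin = 0L,
             missing_destination = 0L, missing_sex = 0L)
  keep <- !is.na(cohort$age)
  drops["missing_age"] <- sum(!keep)
  k2 <- keep & cohort$age >= min_age
  drops["under_min_age"] <- sum(keep) - sum(k2, na.rm = TRUE)
  k3 <- k2 & !is.na(cohort$origin)
  drops["missing_origin"] <- sum(k2, na.rm = TRUE) - sum(k3, na.rm = TRUE)
  k4 <- k3 & !is.na(cohort$destination)
  drops["missing_destination"] <- sum(k3, na.rm = TRUE) - sum(k4, na.rm = TRUE)
  k5 <- k4 & !is.na(cohort$sex)
  drops["missing_sex"] <- sum(k4, na.rm = TRUE) - sum(k5, na.rm = TRUE)
  out <- cohort[which(k5), , drop = FALSE]
  if (nrow(out) == 0L) stop_validation("no rows remain after analytic-sample filters")
  message(sprintf("analytic sample: %d of %d rows retained (%s)",
                  nrow(out), n0,
                  paste(sprintf("%s=%d", names(drops), drops), collapse = ", ")))
  attr(out, "exclusions") <- drops
  out
}

#' Encode mobility dummies for an origin/destination pair
#'
#' Given origin and destination class codes, builds the dummy variables of
#' the four model specifications: `none` (no columns), `any` (mobile),
#' `direction` (upward, downward), `steps` (one-/two-step upward and
#' downward). Immobile persons have all dummies zero; at most one step dummy
#' is ever set.
#'
#' @param origin,destination vectors coercible by [class_code()].
#' @param scheme one of `"none"`, `"any"`, `"direction"`, `"steps"`.
#' @return data frame of 0/1 dummy columns (zero columns for `"none"`).
#' @export
encode_mobility <- function(origin, destination,
                            scheme = c("none", "any", "direction", "steps")) {
  scheme <- match.arg(scheme)
  o <- as.integer(class_code(origin))
  d <- as.integer(class_code(destination))
  if (anyNA(o) || anyNA(d)) stop_validation("missing class codes")
  step <- d - o
  out <- switch(scheme,
    none = data.frame(row.names = seq_along(o)),
    any = data.frame(mobile = as.integer(step != 0L)),
    direction = data.frame(upward = as.integer(step > 0L),
                           downward = as.integer(step < 0L)),
    steps = data.frame(up1 = as.integer(step == 1L),
                       up2 = as.integer(step == 2L),
                       down1 = as.integer(step == -1L),
                       down2 = as.integer(step == -2L)))
  out
}

#' Standardize the age covariates
#'
#' Adds `z_age` (age centred and scaled by the sample SD, n-1 denominator)
#' and `z_age2` (the square of the standardized age, squared after
#' standardizing) over the rows of `cohort`. Standardization is over the
#' sample given, so call this after [filter_analytic_sample()] (and within
#' each stratum when stratifying).
#'
#' @param cohort data frame with an `age` column.
#' @return `cohort` with `z_age` and `z_age2` columns added/replaced.
#' @export
standardize_covariates <- function(cohort) {
  age <- cohort$age
  if (length(unique(age)) < 2L) stop_validation("need >= 2 distinct ages to standardize")
  s <- stats::sd(age)
  if (s == 0) stop_validation("zero age SD")
  cohort$z_age <- (age - mean(age)) / s
  cohort$z_age2 <- cohort$z_age^2
  cohort
}

#' Split a cohort into birth-year strata
#'
#' Used for the cohort-effect sensitivity analysis: splits at a birth-year
#' cutoff (default 1956, the study median) into an "old" and a "young"
#' stratum and re-standardizes the age covariates within each.
#'
#' @param cohort data frame with `birth_year` and `age` columns.
#' @param cutoff birth-year cutoff.
#' @param young_includes_cutoff if `TRUE` (default) persons born exactly in
#'   the cutoff year go to the young stratum.
#' @return named list with elements `old` and `young`.
#' @export
split_birth_cohort <- function(cohort, cutoff = 1956, young_includes_cutoff = TRUE) {
  if (!"birth_year" %in% names(cohort)) stop_validation("cohort lacks birth_year")
  young <- if (young_includes_cutoff) cohort$birth_year >= cutoff else cohort$birth_year > cutoff
  list(old = standardize_covariates(cohort[!young, , drop = FALSE]),
       young = standardize_covariates(cohort[young, , drop = FALSE]))
}
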