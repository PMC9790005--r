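# Published descriptive statistics of the UK Household Longitudinal Study
# (2010-2012) epigenetics subsample, used as the template for the synthetic
# generator and as reproducible in-table arithmetic checks.

#' Origin-by-destination cell counts of the UKHLS epigenetics subsample
#'
#' The published 3x3 sample-size panel (origins in rows, destinations in
#' columns; total n = 3140). These counts are the default cell structure of
#' [generate_cohort()].
#'
#' @return 3x3 integer matrix with class-level dimnames.
#' @export
ukhls_cell_counts <- function() {
  m <- matrix(c(432L, 234L, 302L,
                467L, 466L, 903L,
                42L,  76L,  218L),
              nrow = 3, byrow = TRUE,
              dimnames = list(origin = class_levels(),
                              destination = class_levels()))
  m
}

#' Published age-acceleration cross-tabulation (UKHLS, 2010-2012)
#'
#' The printed 2-dp arithmetic means of age acceleration by origin and
#' destination class for the four predictors (Horvath, Hannum, Phenoage,
#' DunedinPoAm), together with the printed Total row/column/grand entries.
#' Used to check that [marginal_from_cells()] reconstructs the printed
#' marginals from the printed cells and counts.
#'
#' @return named list, one element per predictor; each a list with 3x3
#'   `cells` and printed `row_totals`, `col_totals`, `grand`.
#' @export
ukhls_crosstab <- function() {
  lv <- class_levels()
  mk <- function(cells, row, col, grand) {
    m <- matrix(cells, nrow = 3, byrow = TRUE,
                dimnames = list(origin = lv, destination = lv))
    list(cells = m,
         row_totals = stats::setNames(row, lv),
         col_totals = stats::setNames(col, lv),
         grand = grand)
  }
  list(
    horvath = mk(c(0.05, 0.37, 0.06,
                   0.02, -0.29, 0.01,
                   0.38, -0.55, 0.05),
                 row = c(0.13, -0.06, -0.04),
                 col = c(0.05, -0.11, 0.03), grand = 0.00),
    hannum = mk(c(0.18, 0.30, 0.44,
                  -0.05, -0.64, 0.13,
                  -0.15, -0.90, -0.03),
                row = c(0.29, -0.11, -0.24),
                col = c(0.05, -0.38, 0.17), grand = 0.00),
    phenoage = mk(c(0.97, 0.67, 0.11,
                    0.29, -0.76, -0.36,
                    0.70, 0.36, -0.57),
                  row = c(0.63, -0.30, -0.20),
                  col = c(0.62, -0.22, -0.29), grand = 0.00),
    dunedinpoam = mk(c(0.98, 0.59, -0.37,
                       0.70, -0.38, -0.46,
                       0.20, -0.32, -0.79),
                     row = c(0.46, -0.14, -0.56),
                     col = c(0.81, -0.08, -0.49), grand = 0.00))
}

#' Published sample accounting of the UKHLS epigenetics subsample
#'
#' Totals and birth-cohort strata as printed: overall n and mean age (SD),
#' the old (born before 1956) and young (born in or after 1956) strata with
#' their ns, percentages and mean ages, and the sex split.
#'
#' @return nested list of the printed values.
#' @export
ukhls_sample_accounting <- function() {
  list(n_total = 3140L,
       mean_age = 54.5, sd_age = 14.03,
       old = list(n = 1522L, pct = 48.5, mean_age = 66.6),
       young = list(n = 1618L, pct = 51.5, mean_age = 43.1),
       female = list(n = 1752L, pct = 55.8),
       male = list(n = 1388L, pct = 44.2))
}
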