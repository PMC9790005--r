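# Descriptive surfaces: origin-by-destination cross-tabs of age
# acceleration with n-weighted marginals, group mean comparisons, and the
# restricted mobile-versus-immobile OLS contrasts.

#' Cross-tabulate mean age acceleration by origin and destination class
#'
#' @param outcome numeric per-person outcome (age acceleration).
#' @param origin,destination class codes (see [class_code()]).
#' @param label outcome label carried into the result.
#' @return object of class `aa_crosstab`: list with 3x3 `cell_means`,
#'   `cell_ns`, and n-weighted `row_totals`, `col_totals`, `grand`. Empty
#'   cells have mean `NA` and n 0.
#' @export
crosstab_means <- function(outcome, origin, destination, label = "outcome") {
  o <- class_code(origin); d <- class_code(destination)
  if (anyNA(outcome) || anyNA(o) || anyNA(d)) {
    stop_validation("missing outcome or class data")
  }
  lv <- class_levels()
  cell_ns <- matrix(0L, 3, 3, dimnames = list(origin = lv, destination = lv))
  cell_means <- matrix(NA_real_, 3, 3, dimnames = dimnames(cell_ns))
  for (i in 1:3) for (j in 1:3) {
    sel <- as.integer(o) == i & as.integer(d) == j
    cell_ns[i, j] <- sum(sel)
    if (any(sel)) cell_means[i, j] <- mean(outcome[sel])
  }
  marg <- marginal_from_cells(cell_means, cell_ns)
  structure(c(list(cell_means = cell_means, cell_ns = cell_ns,
                   label = label), marg),
            class = "aa_crosstab")
}

#' Marginal means from cell means and cell counts
#'
#' Recomputes the Total row/column/grand entries of an
#' origin-by-destination table as cell-n-weighted means of the cells.
#'
#' @param cell_means 3x3 numeric matrix of cell means (`NA` allowed where
#'   the corresponding n is 0).
#' @param cell_ns 3x3 non-negative integer matrix of cell counts.
#' @return list with `row_totals`, `col_totals`, `grand` (full precision)
#'   and `row_totals_2dp`, `col_totals_2dp`, `grand_2dp` rounded half away
#'   from zero to 2 decimals.
#' @export
marginal_from_cells <- function(cell_means, cell_ns) {
  cell_means <- as.matrix(cell_means); cell_ns <- as.matrix(cell_ns)
  stopifnot(all(dim(cell_means) == c(3, 3)), all(dim(cell_ns) == c(3, 3)))
  if (any(cell_ns < 0)) stop_validation("negative cell count")
  if (any(cell_ns > 0 & is.na(cell_means))) {
    stop_validation("cell with n > 0 but missing mean")
  }
  w <- cell_ns
  s <- cell_means * w
  s[w == 0] <- 0
  row_totals <- rowSums(s) / rowSums(w)
  col_totals <- colSums(s) / colSums(w)
  grand <- sum(s) / sum(w)
  list(row_totals = row_totals, col_totals = col_totals, grand = grand,
       row_totals_2dp = round_half_out(row_totals),
       col_totals_2dp = round_half_out(col_totals),
       grand_2dp = round_half_out(grand))
}

#' @export
print.aa_crosstab <- function(x, digits = 2, ...) {
  cat(sprintf("Mean %s by origin (rows) and destination (columns) class\n",
              x$label))
  M <- cbind(x$cell_means, Total = x$row_totals)
  M <- rbind(M, Total = c(x$col_totals, x$grand))
  print(round_half_out(M, digits))
  cat("cell n:\n")
  N <- rbind(cbind(x$cell_ns, Total = rowSums(x$cell_ns)),
             Total = c(colSums(x$cell_ns), sum(x$cell_ns)))
  print(N)
  invisible(x)
}

#' Write a cross-tab as delimited text
#'
#' @param ct an `aa_crosstab`.
#' @param path output path (tab-delimited; means block then counts block).
#' @return `path`, invisibly.
#' @export
write_crosstab <- function(ct, path) {
  M <- cbind(ct$cell_means, Total = ct$row_totals)
  M <- rbind(M, Total = c(ct$col_totals, ct$grand))
  N <- rbind(cbind(ct$cell_ns, Total = rowSums(ct$cell_ns)),
             Total = c(colSums(ct$cell_ns), sum(ct$cell_ns)))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# mean ", ct$label), con)
  utils::write.table(data.frame(origin = rownames(M), M, check.names = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("# cell n", con)
  utils::write.table(data.frame(origin = rownames(N), N, check.names = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Two-group t-test or one-way ANOVA across groups
#'
#' Two groups are compared with the classical pooled-variance two-sample
#' t-test; more than two with a one-way ANOVA F-test.
#'
#' @param outcome numeric vector.
#' @param group factor/character grouping with each group n >= 2.
#' @return list with `method` (`"t"` or `"anova"`), `statistic`, `df`,
#'   `p_value`, and the per-group `means`.
#' @export
group_tests <- function(outcome, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop_validation("need >= 2 groups")
  ns <- table(group)
  if (any(ns < 2L)) {
    stop_validation("group(s) with n < 2: ",
                    paste(names(ns)[ns < 2L], collapse = ", "))
  }
  means <- tapply(outcome, group, mean)
  if (nlevels(group) == 2L) {
    tt <- stats::t.test(outcome ~ group, var.equal = TRUE)
    list(method = "t", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value, means = means)
  } else {
    an <- stats::anova(stats::aov(outcome ~ group))
    list(method = "anova", statistic = an[["F value"]][1L],
         df = an$Df[1:2], p_value = an[["Pr(>F)"]][1L], means = means)
  }
}

#' Restricted mobile-versus-immobile OLS comparison
#'
#' Subsets the sample to one mobile group and its immobile reference group
#' and fits OLS of age acceleration on the mobile-group indicator plus sex,
#' standardized age and squared standardized age:
#' * `"down_vs_stable_advantaged"`: downwardly mobile vs persons immobile
#'   in the advantaged class;
#' * `"up_vs_stable_disadvantaged"`: upwardly mobile vs persons immobile in
#'   the disadvantaged class.
#'
#' @param data data frame with columns `origin`, `destination`, `sex`,
#'   `z_age`, `z_age2` and the outcome column.
#' @param outcome name of the outcome column (age acceleration).
#' @param comparison which restricted contrast to estimate.
#' @return list with `comparison`, `estimate` (mobile-group coefficient),
#'   `ci` (95%), `n`, `n_mobile`, `n_immobile`, and the full coefficient
#'   table `coefficients`.
#' @export
restricted_mobility_ols <- function(data, outcome = "acceleration",
                                    comparison = c("down_vs_stable_advantaged",
                                                   "up_vs_stable_disadvantaged")) {
  comparison <- match.arg(comparison)
  o <- as.integer(class_code(data$origin))
  d <- as.integer(class_code(data$destination))
  if (comparison == "down_vs_stable_advantaged") {
    mobile <- d < o
    immobile <- o == 3L & d == 3L
  } else {
    mobile <- d > o
    immobile <- o == 1L & d == 1L
  }
  if (!any(mobile)) stop_validation("empty mobile group for ", comparison)
  if (!any(immobile)) stop_validation("empty immobile reference group for ", comparison)
  sub <- data[mobile | immobile, , drop = FALSE]
  sub$mobile_group <- as.integer(mobile[mobile | immobile])
  fml <- stats::reformulate(c("mobile_group", "sex", "z_age", "z_age2"),
                            response = outcome)
  fit <- stats::lm(fml, data = sub)
  ci <- suppressWarnings(stats::confint(fit, "mobile_group", level = 0.95))
  ci[is.na(ci)] <- stats::coef(fit)["mobile_group"]  # zero-residual fits
  list(comparison = comparison,
       estimate = unname(stats::coef(fit)["mobile_group"]),
       ci = c(lower = ci[1L], upper = ci[2L]),
       n = nrow(sub), n_mobile = sum(mobile), n_immobile = sum(immobile),
       coefficients = summary(fit)$coefficients)
}
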