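# Age acceleration: residuals of DNAm age regressed on chronological age,
# optionally adjusting for plate batch (categorical) and estimated cell
# composition. A positive residual means the sample's methylation profile
# looks older than its chronological age predicts.

#' Residualize DNAm age on chronological age (and batch, cell composition)
#'
#' Fits ordinary least squares of DNAm age on an intercept, chronological
#' age, plate dummies (first level as reference) and cell-fraction columns,
#' and returns the residuals as the per-sample age acceleration. Residuals
#' have mean zero over the fitted sample and are orthogonal to every
#' regressor; they should be recomputed after any sample exclusion so the
#' analytic-sample mean re-zeroes.
#'
#' @param dnam_age numeric vector of DNAm ages (or pace values), named by
#'   sample or aligned with the other arguments.
#' @param chron_age numeric vector of chronological ages.
#' @param plate optional factor/character of plate batch labels.
#' @param cells optional samples x cell-types matrix of fractions
#'   (see [estimate_cell_fractions()]).
#' @param clock label carried into the result.
#' @return object of class `acceleration_result`: list with `sample_ids`,
#'   `clock`, `dnam_age`, `acceleration` (the residuals) and the fitted
#'   `coefficients` table.
#' @export
residualize_age <- function(dnam_age, chron_age, plate = NULL, cells = NULL,
                            clock = "clock") {
  n <- length(dnam_age)
  if (length(chron_age) != n) stop_validation("dnam_age and chron_age lengths differ")
  ids <- names(dnam_age) %||% as.character(seq_len(n))
  X <- cbind("(Intercept)" = rep(1, n), chron_age = as.numeric(chron_age))
  if (!is.null(plate)) {
    plate <- factor(plate)
    if (nlevels(plate) > 1L) {
      P <- stats::model.matrix(~plate)[, -1L, drop = FALSE]
      X <- cbind(X, P)
    }
  }
  if (!is.null(cells)) {
    cells <- as.matrix(cells)
    if (nrow(cells) != n) stop_validation("cells must have one row per sample")
    X <- cbind(X, cells)
  }
  if (anyNA(X) || anyNA(dnam_age)) stop_validation("missing values among outcome or regressors")
  if (length(unique(chron_age)) < 2L) stop_validation("need >= 2 distinct ages")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop_validation("singular design; aliased terms: ",
                    paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qx, dnam_age)
  res <- as.numeric(dnam_age - X %*% beta)
  structure(list(sample_ids = ids,
                 clock = clock,
                 dnam_age = stats::setNames(as.numeric(dnam_age), ids),
                 acceleration = stats::setNames(res, ids),
                 coefficients = data.frame(term = colnames(X),
                                           estimate = as.numeric(beta))),
            class = "acceleration_result")
}

#' @export
print.acceleration_result <- function(x, ...) {
  cat(sprintf("<age acceleration '%s': %d samples, mean %.2e, SD %.3f>\n",
              x$clock, length(x$acceleration), mean(x$acceleration),
              stats::sd(x$acceleration)))
  invisible(x)
}

#' Write acceleration results to delimited text
#'
#' @param results an `acceleration_result` or list of them (one per clock).
#' @param path output path (tab-delimited, columns sample_id, clock,
#'   dnam_age, acceleration).
#' @return `path`, invisibly.
#' @export
write_acceleration <- function(results, path) {
  if (inherits(results, "acceleration_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_ids, clock = r$clock,
               dnam_age = unname(r$dnam_age),
               acceleration = unname(r$acceleration))
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
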