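# Epigenetic clock definitions and their evaluation on beta matrices.
#
# A clock is a fixed linear predictor of age (or aging pace):
#   DNAm age_j = intercept + sum_i beta_ij * coef_i
# over the clock's CpG probe set. Probes absent from the measured array are
# dropped from the sum without rescaling, and the count of dropped probes is
# reported, so the usual situation of a handful of training-array probes
# missing from EPIC data is visible rather than silent.

#' Construct a clock definition
#'
#' @param coefficients named numeric vector, one finite coefficient per CpG
#'   probe ID; may be empty for an intercept-only clock.
#' @param intercept finite numeric intercept (years, or pace units for
#'   pace-of-aging predictors).
#' @param name text label used in outputs.
#' @return object of class `clock_definition` with elements `name`,
#'   `intercept`, `coefficients`, and probe count `m`.
#' @export
clock_definition <- function(coefficients, intercept, name = "clock") {
  coefficients <- unlist(coefficients)
  if (length(coefficients) == 0L) {
    coefficients <- stats::setNames(numeric(0), character(0))
  }
  if (is.null(names(coefficients)) && length(coefficients) > 0L) {
    stop_validation("clock coefficients must be named by probe ID")
  }
  if (anyDuplicated(names(coefficients))) {
    stop_format("duplicate probe IDs in clock: ",
                paste(unique(names(coefficients)[duplicated(names(coefficients))]),
                      collapse = ", "))
  }
  if (!all(is.finite(coefficients))) stop_validation("non-finite clock coefficient")
  if (length(intercept) != 1L || !is.finite(intercept)) {
    stop_validation("intercept must be a single finite number")
  }
  structure(list(name = as.character(name),
                 intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 m = length(coefficients)),
            class = "clock_definition")
}

#' @export
print.clock_definition <- function(x, ...) {
  cat(sprintf("<clock '%s': intercept %.4g, %d probes>\n",
              x$name, x$intercept, x$m))
  invisible(x)
}

#' Read a clock coefficient file
#'
#' Clock files are two-column delimited text (comma or tab, auto-detected)
#' with a header, columns `probe` and `coefficient`. Exactly one row must
#' carry the reserved intercept label (default `"(Intercept)"`); every other
#' row is a per-probe coefficient.
#'
#' @param path path to the file.
#' @param name clock label; defaults to the file name without extension.
#' @param intercept_label reserved probe label marking the intercept row.
#' @return a [clock_definition()].
#' @export
read_clock <- function(path, name = NULL, intercept_label = "(Intercept)") {
  if (!file.exists(path)) stop_validation("clock file not found: ", path)
  delim <- detect_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2L) stop_format("clock file needs columns probe, coefficient: ", path)
  probe <- tab[[1L]]
  val <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(val)) {
    stop_format("non-numeric coefficient for probe(s): ",
                paste(probe[is.na(val)], collapse = ", "))
  }
  is_int <- probe == intercept_label
  if (sum(is_int) == 0L) stop_format("clock file has no '", intercept_label, "' row")
  if (sum(is_int) > 1L) stop_format("clock file has multiple intercept rows")
  if (anyDuplicated(probe[!is_int])) {
    stop_format("duplicate probe rows: ",
                paste(unique(probe[!is_int][duplicated(probe[!is_int])]),
                      collapse = ", "))
  }
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  clock_definition(stats::setNames(val[!is_int], probe[!is_int]),
                   intercept = val[is_int], name = name)
}

#' Write a clock definition to delimited text
#'
#' @param clock a [clock_definition()].
#' @param path output path (`.csv` comma format).
#' @param intercept_label label for the intercept row.
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path, intercept_label = "(Intercept)") {
  df <- data.frame(probe = c(intercept_label, names(clock$coefficients)),
                   coefficient = c(clock$intercept, unname(clock$coefficients)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a methylation beta matrix
#'
#' Delimited text (comma or tab, auto-detected), first column CpG probe ID,
#' header row of sample IDs; `.gz` files are read transparently. Values must
#' lie in \[0, 1\] or be missing.
#'
#' @param path path to the file.
#' @return numeric matrix, probes in rows (rownames), samples in columns
#'   (colnames).
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop_validation("beta matrix file not found: ", path)
  # connection-based read handles .gz transparently
  first <- readLines(gzfile(path), n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(gzfile(path), header = TRUE, sep = delim,
                           check.names = FALSE, row.names = 1L,
                           comment.char = "")
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  validate_beta_matrix(m)
  m
}

#' Write a beta matrix to delimited text
#'
#' @param betas probes x samples matrix with dimnames.
#' @param path output path; a `.gz` suffix writes gzip-compressed text.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  df <- data.frame(probe = rownames(betas), betas, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a beta matrix
#'
#' @param betas probes x samples numeric matrix.
#' @param on_invalid `"error"` (default) or `"warn"` for out-of-range values.
#' @return the matrix, invisibly.
#' @export
validate_beta_matrix <- function(betas, on_invalid = c("error", "warn")) {
  on_invalid <- match.arg(on_invalid)
  if (!is.matrix(betas) || !is.numeric(betas)) {
    stop_validation("betas must be a numeric matrix")
  }
  if (is.null(rownames(betas)) || is.null(colnames(betas))) {
    stop_validation("betas must carry probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(betas))) stop_validation("duplicate probe IDs")
  if (anyDuplicated(colnames(betas))) stop_validation("duplicate sample IDs")
  bad <- !is.na(betas) & (betas < 0 | betas > 1)
  if (any(bad)) {
    msg <- sprintf("%d beta value(s) outside [0, 1]", sum(bad))
    if (on_invalid == "error") stop_validation(msg) else warning(msg, call. = FALSE)
  }
  invisible(betas)
}

#' Evaluate a clock on a beta matrix
#'
#' Computes, for each sample j,
#' `intercept + sum over clock probes present in the matrix of beta_ij * coef_i`.
#' Clock probes absent from the matrix are dropped from the sum with no
#' rescaling and counted in `probes_missing`. A missing (`NA`) beta for a
#' present probe drops that term for that sample only.
#'
#' @param betas probes x samples numeric matrix (see [read_beta_matrix()]).
#' @param clock a [clock_definition()].
#' @param on_invalid passed to [validate_beta_matrix()].
#' @return object of class `clock_result`: list with `sample_ids`, named
#'   numeric `dnam_age`, `probes_used`, `probes_missing`,
#'   `missing_probe_ids`, `na_terms_dropped` (per sample) and `clock` name.
#' @export
compute_dnam_age <- function(betas, clock, on_invalid = c("error", "warn")) {
  validate_beta_matrix(betas, on_invalid)
  stopifnot(inherits(clock, "clock_definition"))
  probes <- names(clock$coefficients)
  present <- probes %in% rownames(betas)
  missing_ids <- probes[!present]
  nsamp <- ncol(betas)
  if (clock$m > 0L && !any(present)) {
    warning(sprintf("clock '%s': all %d probes absent from matrix; returning intercept",
                    clock$name, clock$m), call. = FALSE)
    dnam <- rep(clock$intercept, nsamp)
    na_dropped <- integer(nsamp)
  } else if (clock$m == 0L) {
    dnam <- rep(clock$intercept, nsamp)
    na_dropped <- integer(nsamp)
  } else {
    B <- betas[probes[present], , drop = FALSE]
    contrib <- B * clock$coefficients[present]
    na_dropped <- colSums(is.na(contrib))
    if (any(na_dropped > 0L)) {
      message(sprintf("clock '%s': dropped %d NA beta term(s) across %d sample(s)",
                      clock$name, sum(na_dropped), sum(na_dropped > 0L)))
    }
    dnam <- clock$intercept + colSums(contrib, na.rm = TRUE)
  }
  structure(list(sample_ids = colnames(betas),
                 dnam_age = stats::setNames(as.numeric(dnam), colnames(betas)),
                 probes_used = sum(present),
                 probes_missing = length(missing_ids),
                 missing_probe_ids = missing_ids,
                 na_terms_dropped = stats::setNames(as.integer(na_dropped),
                                                    colnames(betas)),
                 clock = clock$name),
            class = "clock_result")
}

#' @export
print.clock_result <- function(x, ...) {
  cat(sprintf("<clock result '%s': %d samples, %d/%d probes used>\n",
              x$clock, length(x$sample_ids), x$probes_used,
              x$probes_used + x$probes_missing))
  invisible(x)
}
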