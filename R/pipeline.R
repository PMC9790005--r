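# End-to-end pipeline: clocks -> cell composition -> residualization ->
# analytic-sample filtering -> mobility encoding -> DRM models 1-4 ->
# descriptives, with validation up front and a sample-accounting log.

#' Run the full analysis pipeline
#'
#' Orchestrates the study workflow. Inputs may be in-memory objects or file
#' paths (all path validation happens before any computation, and failures
#' are reported together). For each clock the pipeline computes DNAm age,
#' residualizes it on chronological age, plate and (if a reference is
#' given) estimated cell fractions, filters to the analytic sample,
#' standardizes the age covariates, fits the four DRM specifications
#' (no-mobility, any-mobility, direction, steps), and writes the
#' acceleration table, per-clock cross-tabs, per-model JSON fit reports, a
#' model-comparison table, and a log recording n at every exclusion step.
#'
#' @param betas probes x samples matrix or path (see [read_beta_matrix()]).
#' @param phenotype data frame or path; must contain `sample_id`, `age`,
#'   `sex`, `plate`, `origin`, `destination` (and optionally `birth_year`).
#' @param clocks a [clock_definition()], list of them, or character vector
#'   of clock-file paths.
#' @param reference optional probes x cell-types matrix or path.
#' @param out_dir output directory; created if needed. `NULL` skips file
#'   output.
#' @param schemes subset of `c("none", "any", "direction", "steps")`.
#' @param min_age analytic-sample minimum age.
#' @param covariate_terms phenotype columns entering every DRM as
#'   covariates (after standardization adds `z_age`, `z_age2`).
#' @return invisibly, a list with `acceleration` (per clock),
#'   `cell_fractions`, `analytic` (the filtered, standardized cohort with
#'   per-clock acceleration columns), `crosstabs`, `fits` (clock x scheme),
#'   `comparison` (per clock), `log` (character vector).
#' @export
run_pipeline <- function(betas, phenotype, clocks, reference = NULL,
                         out_dir = NULL,
                         schemes = c("none", "any", "direction", "steps"),
                         min_age = 25,
                         covariate_terms = c("sex", "z_age", "z_age2")) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  # -- validate all file inputs before touching any of them
  problems <- character(0)
  chk <- function(x, what) {
    if (is.character(x)) {
      for (p in x) if (!file.exists(p)) {
        problems <<- c(problems, sprintf("%s file not found: %s", what, p))
      }
    }
  }
  chk(betas, "beta matrix"); chk(phenotype, "phenotype")
  if (is.character(clocks)) chk(clocks, "clock")
  chk(reference, "reference")
  if (length(problems)) {
    stop_validation("input validation failed:\n  ",
                    paste(problems, collapse = "\n  "))
  }

  if (is.character(betas)) betas <- read_beta_matrix(betas)
  if (is.character(phenotype)) {
    phenotype <- utils::read.table(phenotype, header = TRUE,
                                   sep = detect_delim(phenotype),
                                   stringsAsFactors = FALSE)
  }
  if (inherits(clocks, "clock_definition")) clocks <- list(clocks)
  if (is.character(clocks)) clocks <- lapply(clocks, read_clock)
  names(clocks) <- vapply(clocks, `[[`, character(1), "name")
  if (is.character(reference)) reference <- read_cell_reference(reference)

  need <- c("sample_id", "age", "sex", "origin", "destination", "plate")
  miss <- setdiff(need, names(phenotype))
  if (length(miss)) stop_validation("phenotype lacks columns: ",
                                    paste(miss, collapse = ", "))
  shared <- intersect(colnames(betas), phenotype$sample_id)
  log <- sprintf("samples: %d in betas, %d in phenotype, %d shared",
                 ncol(betas), nrow(phenotype), length(shared))
  if (length(shared) == 0L) stop_validation("no samples shared between betas and phenotype")
  betas <- betas[, shared, drop = FALSE]
  phenotype <- phenotype[match(shared, phenotype$sample_id), , drop = FALSE]
  phenotype$origin <- class_code(phenotype$origin)
  phenotype$destination <- class_code(phenotype$destination)

  cells <- NULL
  if (!is.null(reference)) {
    cells <- estimate_cell_fractions(betas, reference)
    log <- c(log, sprintf("cell fractions estimated for %d samples on %d probes",
                          nrow(cells), attr(cells, "n_probes")))
  }

  accel <- list()
  for (nm in names(clocks)) {
    cr <- compute_dnam_age(betas, clocks[[nm]])
    log <- c(log, sprintf("clock %s: %d/%d probes used", nm, cr$probes_used,
                          cr$probes_used + cr$probes_missing))
    accel[[nm]] <- cr
  }

  # analytic sample first, then residualize within it so means re-zero
  cohort <- phenotype
  flt <- withCallingHandlers(
    filter_analytic_sample(cohort, min_age = min_age),
    message = function(m) {
      log <<- c(log, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  flt <- standardize_covariates(flt)
  log <- c(log, sprintf("analytic n = %d", nrow(flt)))
  idx <- match(flt$sample_id, shared)

  accel_res <- list()
  for (nm in names(clocks)) {
    accel_res[[nm]] <- residualize_age(
      accel[[nm]]$dnam_age[idx], flt$age,
      plate = flt$plate,
      cells = if (!is.null(cells)) cells[idx, , drop = FALSE],
      clock = nm)
    flt[[paste0("accel_", nm)]] <- unname(accel_res[[nm]]$acceleration)
  }

  crosstabs <- list(); fits <- list(); comparisons <- list()
  for (nm in names(clocks)) {
    y <- flt[[paste0("accel_", nm)]]
    crosstabs[[nm]] <- crosstab_means(y, flt$origin, flt$destination,
                                      label = paste0(nm, " acceleration"))
    covs <- flt[, covariate_terms, drop = FALSE]
    fits[[nm]] <- lapply(stats::setNames(schemes, schemes), function(sc) {
      fit_drm(y, flt$origin, flt$destination, covariates = covs,
              scheme = sc, model = paste(nm, sc, sep = "_"))
    })
    log <- c(log, sprintf("clock %s: fitted %d DRM model(s), n = %d",
                          nm, length(schemes), nrow(flt)))
    if (length(schemes) > 1L) comparisons[[nm]] <- compare_drm(fits[[nm]])
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_acceleration(accel_res, file.path(out_dir, "acceleration.tsv"))
    for (nm in names(clocks)) {
      write_crosstab(crosstabs[[nm]],
                     file.path(out_dir, sprintf("crosstab_%s.tsv", nm)))
      for (sc in schemes) {
        jsonlite::write_json(drm_report(fits[[nm]][[sc]]),
                             file.path(out_dir, sprintf("drm_%s_%s.json", nm, sc)),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      if (!is.null(comparisons[[nm]])) {
        utils::write.table(comparisons[[nm]],
                           file.path(out_dir,
                                     sprintf("model_comparison_%s.tsv", nm)),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    writeLines(log, file.path(out_dir, "pipeline_log.txt"))
  }
  invisible(list(acceleration = accel_res, cell_fractions = cells,
                 analytic = flt, crosstabs = crosstabs, fits = fits,
                 comparison = comparisons, log = log))
}
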