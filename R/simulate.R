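# Synthetic cohort generation.
#
# Every generator is a pure function of its arguments including the seed.
# The defaults emulate the study conditions: the origin-by-destination cell
# counts of the published sample-size panel (n = 3140), age ~ N(54.5, 14^2)
# truncated at 25, 55.8% female, and outcomes generated under the diagonal
# reference model with chosen mixing weight, diagonal effects, covariate
# effects and Gaussian noise. Class-cell membership is assigned by exact
# counts (not multinomial draws) so marginal checks are exact.

#' Generate a synthetic cohort with DRM-structured outcomes
#'
#' Assigns origin/destination class by exact per-cell counts, draws age
#' (truncated normal), sex, and plate, standardizes the age covariates over
#' the generated sample, and generates the outcome
#' `y = beta0 + p delta_origin + (1 - p) delta_destination + covariate
#' effects + mobility effects + N(0, sigma^2)`.
#'
#' @param cell_counts 3x3 matrix of origin x destination counts (default:
#'   the published panel, [ukhls_cell_counts()], n = 3140).
#' @param p true origin weight in \[0, 1\].
#' @param delta length-3 diagonal class effects summing to 0
#'   (disadvantaged, intermediate, advantaged).
#' @param beta0 constant.
#' @param sex_effect additive effect of female sex on the outcome.
#' @param age_effect,age_sq_effect effects of `z_age` and `z_age2`.
#' @param mobility_effects optional named numeric vector of true mobility
#'   effects; recognized names: `mobile`, `upward`, `downward`, `up1`,
#'   `up2`, `down1`, `down2`.
#' @param sigma residual SD of the outcome.
#' @param age_mean,age_sd,age_min truncated-normal age distribution.
#' @param p_female probability of female sex.
#' @param n_plates number of plate batches, assigned uniformly at random.
#' @param assessment_year year used to derive `birth_year` from age.
#' @param seed RNG seed; the output is a deterministic function of all
#'   arguments.
#' @return data frame with columns `sample_id`, `age`, `birth_year`, `sex`,
#'   `plate`, `origin`, `destination`, `z_age`, `z_age2`, `y`, plus
#'   attribute `"truth"` holding the generating parameters.
#' @export
generate_cohort <- function(cell_counts = ukhls_cell_counts(),
                            p = 0.5, delta = c(1, 0, -1), beta0 = 0,
                            sex_effect = -1, age_effect = 0, age_sq_effect = 0,
                            mobility_effects = NULL, sigma = 1,
                            age_mean = 54.5, age_sd = 14, age_min = 25,
                            p_female = 0.558, n_plates = 8,
                            assessment_year = 2011, seed = 1) {
  stopifnot(all(dim(cell_counts) == c(3, 3)), all(cell_counts >= 0),
            p >= 0, p <= 1, length(delta) == 3, abs(sum(delta)) < 1e-8,
            sigma >= 0)
  set.seed(seed)
  lv <- class_levels()
  grid <- expand.grid(origin = 1:3, destination = 1:3)
  counts <- as.vector(cell_counts)  # column-major matches expand.grid order
  o <- rep(grid$origin, counts)
  d <- rep(grid$destination, counts)
  n <- length(o)
  ord <- sample.int(n)  # shuffle so plate assignment is not class-confounded
  o <- o[ord]; d <- d[ord]

  # truncated normal via inverse CDF on a shifted uniform
  u <- stats::runif(n, stats::pnorm(age_min, age_mean, age_sd), 1)
  age <- stats::qnorm(u, age_mean, age_sd)
  sex <- factor(ifelse(stats::rbinom(n, 1, p_female) == 1, "female", "male"),
                levels = c("male", "female"))
  plate <- factor(sprintf("P%02d", sample.int(n_plates, n, replace = TRUE)))

  cohort <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                       age = age,
                       birth_year = as.integer(round(assessment_year - age)),
                       sex = sex, plate = plate,
                       origin = factor(lv[o], levels = lv, ordered = TRUE),
                       destination = factor(lv[d], levels = lv, ordered = TRUE))
  cohort <- standardize_covariates(cohort)

  y <- beta0 + p * delta[o] + (1 - p) * delta[d] +
    sex_effect * (sex == "female") +
    age_effect * cohort$z_age + age_sq_effect * cohort$z_age2
  if (!is.null(mobility_effects)) {
    mob <- cbind(encode_mobility(cohort$origin, cohort$destination, "any"),
                 encode_mobility(cohort$origin, cohort$destination, "direction"),
                 encode_mobility(cohort$origin, cohort$destination, "steps"))
    bad <- setdiff(names(mobility_effects), names(mob))
    if (length(bad)) stop_validation("unknown mobility effect(s): ",
                                     paste(bad, collapse = ", "))
    for (nm in names(mobility_effects)) {
      y <- y + mobility_effects[[nm]] * mob[[nm]]
    }
  }
  if (sigma > 0) y <- y + stats::rnorm(n, 0, sigma)
  cohort$y <- y
  attr(cohort, "truth") <- list(p = p, delta = stats::setNames(delta, lv),
                                beta0 = beta0, sex_effect = sex_effect,
                                age_effect = age_effect,
                                age_sq_effect = age_sq_effect,
                                mobility_effects = mobility_effects,
                                sigma = sigma, seed = seed)
  cohort
}

#' A small all-positive toy clock
#'
#' Positive coefficients are required by [generate_betas()] so that any
#' target in `[intercept, intercept + sum(coefficients)]` is attainable
#' with beta values in \[0, 1\]. Shipped for tests and simulation only;
#' published coefficient sets are user-supplied.
#'
#' @param m number of probes.
#' @param intercept clock intercept.
#' @param total sum of the (positive) coefficients; with `intercept = 0`
#'   the clock can express DNAm ages in `[0, total]`.
#' @param name clock label.
#' @param prefix probe-ID prefix (kept distinct from reference/filler
#'   probes).
#' @param seed RNG seed.
#' @return a [clock_definition()].
#' @export
toy_clock <- function(m = 50, intercept = 0, total = 120, name = "toy",
                      prefix = "cgT", seed = 1) {
  set.seed(seed)
  raw <- stats::runif(m, 0.5, 1.5)
  coefs <- raw / sum(raw) * total
  names(coefs) <- sprintf("%s%05d", prefix, seq_len(m))
  clock_definition(coefs, intercept = intercept, name = name)
}

#' Generate clock-probe betas that invert to given DNAm-age targets
#'
#' Each sample's clock probes are set to the base level
#' `(target - intercept) / sum(coefficients)`, then perturbed by a
#' per-sample zero-sum vector orthogonal to the coefficient vector (so the
#' clock still recovers the target exactly while betas vary probe to
#' probe). Filler probes not in the clock are drawn uniform.
#'
#' @param targets numeric vector of target DNAm ages, named by sample ID.
#' @param clock a [clock_definition()] with all-positive coefficients.
#' @param probe_noise SD of the orthogonal perturbation (0 for constant
#'   rows).
#' @param n_filler number of non-clock filler probes.
#' @param clip_tol targets outside the attainable range by more than this
#'   are an error; within it they are clipped with a message.
#' @param seed RNG seed.
#' @return probes x samples beta matrix.
#' @export
generate_betas <- function(targets, clock, probe_noise = 0.02, n_filler = 50,
                           clip_tol = 1e-8, seed = 1) {
  stopifnot(inherits(clock, "clock_definition"), clock$m > 0)
  w <- clock$coefficients
  if (any(w <= 0)) stop_validation("generate_betas needs an all-positive clock")
  set.seed(seed)
  S <- sum(w)
  ids <- names(targets) %||% sprintf("S%05d", seq_along(targets))
  b <- (targets - clock$intercept) / S
  out_of_range <- b < -clip_tol / S | b > 1 + clip_tol / S
  if (any(out_of_range)) {
    stop_validation(sprintf("%d target(s) outside attainable range [%g, %g]",
                            sum(out_of_range), clock$intercept,
                            clock$intercept + S))
  }
  clipped <- b < 0 | b > 1
  if (any(clipped)) {
    message(sprintf("clipped %d base level(s) to [0, 1]", sum(clipped)))
    b <- pmin(pmax(b, 0), 1)
  }
  m <- clock$m
  n <- length(b)
  B <- matrix(rep(b, each = m), nrow = m,
              dimnames = list(names(w), ids))
  if (probe_noise > 0 && m > 2) {
    E <- matrix(stats::rnorm(m * n), m, n)
    Q <- qr.Q(qr(cbind(w, rep(1, m))))       # span{coefficients, ones}
    E <- E - Q %*% crossprod(Q, E)           # orthogonal complement
    sds <- sqrt(colSums(E^2) / (m - 1))
    E <- sweep(E, 2, ifelse(sds > 0, probe_noise / sds, 0), `*`)
    # shrink each column so the perturbed betas stay inside [0, 1]
    room_hi <- 1 - b; room_lo <- b
    emax <- apply(E, 2, max); emin <- apply(E, 2, min)
    shrink <- pmin(1,
                   ifelse(emax > 0, 0.95 * room_hi / emax, 1),
                   ifelse(emin < 0, 0.95 * room_lo / (-emin), 1))
    B <- B + sweep(E, 2, shrink, `*`)
  }
  if (n_filler > 0) {
    Fm <- matrix(stats::runif(n_filler * n, 0.05, 0.95), n_filler, n,
                 dimnames = list(sprintf("cgF%05d", seq_len(n_filler)), ids))
    B <- rbind(B, Fm)
  }
  B
}

#' Generate a cell-type reference and mixed samples with known fractions
#'
#' Reference columns are drawn uniform in \[0.05, 0.95\]; sample betas are
#' `reference %*% fractions + noise`, clipped to \[0, 1\].
#'
#' @param K number of cell types.
#' @param n_probes probes in the reference.
#' @param true_fractions samples x K matrix (or length-K vector for one
#'   sample) of non-negative fractions with row sums <= 1.
#' @param noise SD of the additive Gaussian measurement noise.
#' @param seed RNG seed.
#' @return list with `reference` (probes x K matrix), `betas` (probes x
#'   samples), and `fractions` (the truth).
#' @export
generate_reference_mixture <- function(K = 3, n_probes = 200,
                                       true_fractions, noise = 0.01,
                                       seed = 1) {
  if (is.null(dim(true_fractions))) {
    true_fractions <- matrix(true_fractions, nrow = 1)
  }
  stopifnot(ncol(true_fractions) == K, all(true_fractions >= 0),
            all(rowSums(true_fractions) <= 1 + 1e-9))
  set.seed(seed)
  R <- matrix(stats::runif(n_probes * K, 0.05, 0.95), n_probes, K,
              dimnames = list(sprintf("cgR%05d", seq_len(n_probes)),
                              sprintf("cell%d", seq_len(K))))
  n <- nrow(true_fractions)
  ids <- rownames(true_fractions) %||% sprintf("S%05d", seq_len(n))
  B <- R %*% t(true_fractions)
  if (noise > 0) B <- B + matrix(stats::rnorm(n_probes * n, 0, noise), n_probes, n)
  B <- pmin(pmax(B, 0), 1)
  colnames(B) <- ids
  rownames(true_fractions) <- ids
  list(reference = R, betas = B, fractions = true_fractions)
}

#' Simulate a complete study: cohort, clock, betas, cell reference
#'
#' Composes the generators into one self-consistent dataset: a cohort with
#' DRM-structured outcomes, a toy clock, per-sample DNAm-age targets
#' `age + plate effect + y` (so the generated outcome is recoverable as
#' the age-acceleration residual), clock-probe betas inverting those
#' targets, cell-reference probes carrying known mixing fractions, and
#' filler probes.
#'
#' @param ... passed to [generate_cohort()].
#' @param clock_m,clock_total toy clock size and coefficient sum.
#' @param plate_effect_sd SD of the per-plate additive shifts on DNAm age.
#' @param probe_noise orthogonal perturbation SD for clock probes.
#' @param K,n_ref_probes,cell_noise cell-reference dimensions and noise.
#' @param n_filler filler probe count.
#' @param seed master seed; sub-generators use fixed offsets of it.
#' @return list with `cohort`, `clock`, `betas`, `reference`,
#'   `cell_fractions` (truth), `dnam_targets`, `plate_effects`.
#' @export
simulate_study <- function(..., clock_m = 50, clock_total = 160,
                           plate_effect_sd = 1, probe_noise = 0.02,
                           K = 3, n_ref_probes = 120, cell_noise = 0.005,
                           n_filler = 30, seed = 1) {
  cohort <- generate_cohort(..., seed = seed)
  n <- nrow(cohort)
  clock <- toy_clock(m = clock_m, intercept = 0, total = clock_total,
                     seed = seed + 101)
  set.seed(seed + 202)
  plate_effects <- stats::setNames(stats::rnorm(nlevels(cohort$plate), 0,
                                                plate_effect_sd),
                                   levels(cohort$plate))
  targets <- stats::setNames(cohort$age +
                               plate_effects[as.character(cohort$plate)] +
                               cohort$y,
                             cohort$sample_id)
  betas_clock <- generate_betas(targets, clock, probe_noise = probe_noise,
                                n_filler = n_filler, seed = seed + 303)
  # cell fractions: normalized gammas scaled to sum 0.95
  set.seed(seed + 404)
  G <- matrix(stats::rgamma(n * K, shape = 4), n, K)
  W <- G / rowSums(G) * 0.95
  rownames(W) <- cohort$sample_id
  mix <- generate_reference_mixture(K = K, n_probes = n_ref_probes,
                                    true_fractions = W, noise = cell_noise,
                                    seed = seed + 505)
  betas <- rbind(betas_clock, mix$betas)
  list(cohort = cohort, clock = clock, betas = betas,
       reference = mix$reference, cell_fractions = W,
       dnam_targets = targets, plate_effects = plate_effects)
}

#' Write a simulated study to delimited text files
#'
#' Emits `phenotype.tsv`, `betas.tsv.gz`, `clock_<name>.csv` and
#' `reference.tsv` under `dir`, in the formats the readers expect.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named list of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    phenotype = file.path(dir, "phenotype.tsv"),
    betas = file.path(dir, "betas.tsv.gz"),
    clock = file.path(dir, paste0(study$clock$name, ".csv")),
    reference = file.path(dir, "reference.tsv"))
  utils::write.table(study$cohort, paths$phenotype, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_beta_matrix(study$betas, paths$betas)
  write_clock(study$clock, paths$clock)
  utils::write.table(data.frame(probe = rownames(study$reference),
                                study$reference, check.names = FALSE),
                     paths$reference, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
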