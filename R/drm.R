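# Diagonal reference models (DRM).
#
# Mobile individuals' expected outcome is a convex combination of the
# immobile (diagonal) means of their origin and destination classes:
#
#   E(Y_ij) = beta0 + p * mu_ii + (1 - p) * mu_jj + X_ij beta
#
# where p in [0, 1] weighs childhood (origin) against adult (destination)
# class. As printed, beta0 together with three diagonal means is
# over-parameterized; identification here uses sum-to-zero class effects
# delta (mu_kk = beta0 + delta_k, sum(delta) = 0) plus the constant, which
# matches the reporting convention in which the three printed class
# estimates sum to ~0.
#
# Estimation is Gaussian maximum likelihood profiled over p: at fixed p the
# model is linear, so the inner fit is closed-form least squares; the
# one-dimensional profile is scanned on a grid and the best grid point
# refined by Brent's method. This is global in p by construction.

.effect_coding <- function() {
  # rows = class rank 1..3; sum-to-zero (effect) coding with 2 free columns
  matrix(c(1, 0,
           0, 1,
           -1, -1), nrow = 3, byrow = TRUE)
}

#' Build the DRM design matrix at a fixed mixing weight
#'
#' The two class-effect columns use sum-to-zero coding in which each person
#' contributes weight `p` to their origin-class coding row and `1 - p` to
#' their destination-class row; immobile persons therefore contribute total
#' weight 1 to their own class. Covariate columns are appended unchanged.
#'
#' @param origin,destination vectors coercible by [class_code()].
#' @param p mixing weight in \[0, 1\] (origin weight).
#' @param X optional numeric matrix/data frame of covariate columns.
#' @return numeric design matrix with columns `(Intercept)`, `delta1`,
#'   `delta2`, then the covariates.
#' @export
build_drm_design <- function(origin, destination, p, X = NULL) {
  o <- as.integer(class_code(origin))
  d <- as.integer(class_code(destination))
  EC <- .effect_coding()
  cls <- p * EC[o, , drop = FALSE] + (1 - p) * EC[d, , drop = FALSE]
  colnames(cls) <- c("delta1", "delta2")
  M <- cbind("(Intercept)" = rep(1, length(o)), cls)
  if (!is.null(X)) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    M <- cbind(M, X)
  }
  M
}

#' Least-squares DRM fit at a fixed mixing weight
#'
#' Closed-form inner step of the profile estimator: ordinary least squares
#' of the outcome on [build_drm_design()] at fixed `p`, with the
#' maximum-likelihood residual variance `sigma2 = RSS / n` and Gaussian
#' log-likelihood `-n/2 (log(2 pi sigma2) + 1)`.
#'
#' @inheritParams build_drm_design
#' @param y numeric outcome vector (age acceleration).
#' @return list with `coefficients` (named; `(Intercept)`, `delta1`,
#'   `delta2`, covariates), `delta` (all three class effects, summing to 0),
#'   `sigma2`, `rss`, `logL`.
#' @export
fit_drm_at_p <- function(y, origin, destination, p, X = NULL) {
  M <- build_drm_design(origin, destination, p, X)
  n <- length(y)
  qm <- qr(M)
  if (qm$rank < ncol(M)) {
    aliased <- colnames(M)[qm$pivot[(qm$rank + 1L):ncol(M)]]
    stop_validation("rank-deficient DRM design at p=", format(p),
                    "; aliased columns: ", paste(aliased, collapse = ", "))
  }
  beta <- qr.coef(qm, y)
  res <- y - as.numeric(M %*% beta)
  rss <- sum(res^2)
  sigma2 <- rss / n
  logL <- if (sigma2 > 0) -n / 2 * (log(2 * pi * sigma2) + 1) else Inf
  delta <- c(beta["delta1"], beta["delta2"], -beta["delta1"] - beta["delta2"])
  names(delta) <- class_levels()
  list(coefficients = beta, delta = delta, sigma2 = sigma2, rss = rss,
       logL = logL, n = n)
}

# negative log-likelihood in the full parameter vector
# theta = (p, delta1, delta2, beta0, beta..., sigma2)
.drm_negll <- function(theta, y, origin, destination, Xnames, X) {
  p <- theta[1L]
  k <- length(theta)
  sigma2 <- theta[k]
  if (sigma2 <= 0) return(Inf)
  coefs <- c("(Intercept)" = unname(theta[4L]), delta1 = unname(theta[2L]),
             delta2 = unname(theta[3L]))
  if (!is.null(X)) {
    coefs <- c(coefs, stats::setNames(unname(theta[5:(k - 1L)]), Xnames))
  }
  M <- build_drm_design(origin, destination, p, X)
  res <- y - as.numeric(M %*% coefs[colnames(M)])
  n <- length(y)
  n / 2 * log(2 * pi * sigma2) + sum(res^2) / (2 * sigma2)
}

#' Fit a diagonal reference model
#'
#' Gaussian maximum likelihood with the origin weight `p` profiled: the
#' log-likelihood is evaluated on the grid `p = 0, 0.01, ..., 1` (closed
#' form at each point), and the best grid point is refined with bounded
#' Brent optimization to tolerance 1e-6. Mobility dummies for the requested
#' scheme are generated internally from origin/destination and appended to
#' the covariates. Standard errors come from the inverse numerical Hessian
#' of the full log-likelihood (including `p` and `sigma2`) at the optimum;
#' Wald confidence intervals for `p` are reported as `NA` when the estimate
#' is at the boundary (within 0.005 of 0 or 1), where Wald theory fails.
#'
#' @param y numeric outcome (age acceleration).
#' @param origin,destination class codes (see [class_code()]).
#' @param covariates optional data frame of covariates (factors are
#'   expanded to treatment dummies; numeric columns passed through).
#' @param scheme mobility specification: `"none"`, `"any"`, `"direction"`
#'   or `"steps"` (the paper's Models 1-4).
#' @param grid_step profile grid spacing for `p`.
#' @param tol Brent convergence tolerance on `p`.
#' @param model optional label carried into reports.
#' @param compute_vcov if `FALSE`, skip the numerical Hessian (standard
#'   errors and CIs become `NA`); useful when only point estimates or
#'   information criteria are needed, e.g. in simulation studies.
#' @return object of class `drm_fit`; see Details. Elements include `p`
#'   (origin weight), `delta` (three class effects summing to zero),
#'   `beta0`, `beta`, `sigma2`, `logL`, `AIC`, `BIC`, `vcov`, `se`, `ci`
#'   (95% Wald), `n`, `k`, `converged`, `boundary`, `profile` (grid data
#'   frame), `profile_flat`.
#' @export
fit_drm <- function(y, origin, destination, covariates = NULL,
                    scheme = c("none", "any", "direction", "steps"),
                    grid_step = 0.01, tol = 1e-6, model = NULL,
                    compute_vcov = TRUE) {
  scheme <- match.arg(scheme)
  origin <- class_code(origin)
  destination <- class_code(destination)
  n <- length(y)
  if (length(origin) != n || length(destination) != n) {
    stop_validation("y, origin, destination lengths differ")
  }
  if (anyNA(y) || anyNA(origin) || anyNA(destination)) {
    stop_validation("missing values in outcome or class codes")
  }
  if (all(origin == destination)) {
    stop_validation("no mobile persons: the mixing weight p is unidentified")
  }

  X <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    X <- stats::model.matrix(~., data = covariates)[, -1L, drop = FALSE]
  }
  mob <- encode_mobility(origin, destination, scheme)
  if (ncol(mob) > 0L) X <- cbind(X, as.matrix(mob))

  grid <- seq(0, 1, by = grid_step)
  gl <- vapply(grid, function(p) {
    fit_drm_at_p(y, origin, destination, p, X)$logL
  }, numeric(1))
  best <- max(gl)
  ties <- which(gl >= best - 1e-9)
  profile_flat <- length(ties) > 1L
  i_best <- ties[1L]  # deterministic: smallest p among ties
  if (profile_flat) {
    warning("flat profile likelihood over p; reporting smallest tied p",
            call. = FALSE)
  }

  lo <- max(0, grid[i_best] - grid_step)
  hi <- min(1, grid[i_best] + grid_step)
  opt <- stats::optimize(function(p) fit_drm_at_p(y, origin, destination, p, X)$logL,
                         interval = c(lo, hi), maximum = TRUE, tol = tol)
  p_hat <- if (opt$objective >= gl[i_best]) opt$maximum else grid[i_best]
  fit <- fit_drm_at_p(y, origin, destination, p_hat, X)

  beta_cov <- fit$coefficients[setdiff(names(fit$coefficients),
                                       c("(Intercept)", "delta1", "delta2"))]
  theta <- c(p = p_hat, delta1 = unname(fit$delta[1L]),
             delta2 = unname(fit$delta[2L]),
             beta0 = unname(fit$coefficients["(Intercept)"]),
             beta_cov, sigma2 = fit$sigma2)
  k <- length(theta)  # p, 2 free deltas, beta0, covariates, sigma2
  logL <- fit$logL
  AIC <- -2 * logL + 2 * k
  BIC <- -2 * logL + k * log(n)
  boundary <- p_hat < 0.005 || p_hat > 0.995

  converged <- is.finite(logL)
  vc <- matrix(NA_real_, k - 1L, k - 1L)
  Xnames <- names(beta_cov)
  if (compute_vcov) {
    H <- tryCatch(
      pracma::hessian(.drm_negll, theta, y = y, origin = origin,
                      destination = destination, Xnames = Xnames, X = X),
      error = function(e) NULL)
    if (!is.null(H)) {
      Vfull <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Vfull)) {
        vc <- Vfull[seq_len(k - 1L), seq_len(k - 1L), drop = FALSE]  # drop sigma2
      }
    }
    if (anyNA(vc)) {
      converged <- FALSE
      warning("DRM vcov unavailable (singular or failed Hessian); fit flagged",
              call. = FALSE)
    }
  }
  par_names <- c("p", "delta1", "delta2", "beta0", Xnames)
  dimnames(vc) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(vc), 0))
  est <- theta[seq_len(k - 1L)]
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  rownames(ci) <- par_names
  if (boundary) ci["p", ] <- NA_real_

  structure(list(p = p_hat, destination_weight = 1 - p_hat,
                 delta = fit$delta,
                 beta0 = unname(fit$coefficients["(Intercept)"]),
                 beta = beta_cov,
                 sigma2 = fit$sigma2,
                 vcov = vc, se = stats::setNames(se, par_names), ci = ci,
                 logL = logL, AIC = AIC, BIC = BIC, n = n, k = k,
                 converged = converged, boundary = boundary,
                 profile = data.frame(p = grid, logL = gl),
                 profile_flat = profile_flat,
                 scheme = scheme,
                 model = model %||% paste0("drm_", scheme),
                 y = y),
            class = "drm_fit")
}

#' @export
print.drm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Diagonal reference model (%s), n = %d\n", x$scheme, x$n))
  fmt <- function(est, se, lo, hi) {
    sprintf("%8.*f  [%.*f, %.*f]", digits, est, digits, lo, digits, hi)
  }
  rows <- rbind(
    data.frame(term = names(x$delta),
               estimate = unname(x$delta),
               lower = c(x$ci["delta1", 1], x$ci["delta2", 1], NA),
               upper = c(x$ci["delta1", 2], x$ci["delta2", 2], NA)),
    data.frame(term = c("origin weight (p)", "destination weight (1-p)"),
               estimate = c(x$p, 1 - x$p),
               lower = c(x$ci["p", 1], 1 - x$ci["p", 2]),
               upper = c(x$ci["p", 2], 1 - x$ci["p", 1])))
  if (length(x$beta)) {
    rows <- rbind(rows, data.frame(term = names(x$beta),
                                   estimate = unname(x$beta),
                                   lower = x$ci[names(x$beta), 1],
                                   upper = x$ci[names(x$beta), 2]))
  }
  rows <- rbind(rows, data.frame(term = "constant", estimate = x$beta0,
                                 lower = x$ci["beta0", 1],
                                 upper = x$ci["beta0", 2]))
  for (i in seq_len(nrow(rows))) {
    cat(sprintf("  %-28s %s\n", rows$term[i],
                ifelse(is.na(rows$lower[i]),
                       sprintf("%8.*f", digits, rows$estimate[i]),
                       fmt(rows$estimate[i], NA, rows$lower[i], rows$upper[i]))))
  }
  cat(sprintf("  logL %.2f, AIC %.1f, BIC %.1f%s%s\n", x$logL, x$AIC, x$BIC,
              if (x$boundary) " [p at boundary]" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
logLik.drm_fit <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
coef.drm_fit <- function(object, ...) {
  c(p = object$p, object$delta[1:2], beta0 = object$beta0, object$beta)
}

#' @export
vcov.drm_fit <- function(object, ...) object$vcov

#' Compare DRM fits by information criteria
#'
#' @param fits list of `drm_fit` objects fitted to the identical sample and
#'   outcome (checked).
#' @param names optional model labels.
#' @return data frame with one row per fit: `model`, `scheme`, `k`, `logL`,
#'   `AIC`, `dAIC`, `BIC`, `dBIC`, `rank_aic`, `rank_bic`, ordered by AIC.
#' @export
compare_drm <- function(fits, names = NULL) {
  if (inherits(fits, "drm_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "drm_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) > 1L) stop_validation("fits have differing n")
  if (length(fits) > 1L) {
    y1 <- fits[[1L]]$y
    same <- vapply(fits[-1L], function(f) isTRUE(all.equal(f$y, y1)),
                   logical(1))
    if (!all(same)) stop_validation("fits have differing outcomes")
  }
  labels <- names %||% vapply(fits, `[[`, character(1), "model")
  df <- data.frame(model = labels,
                   scheme = vapply(fits, `[[`, character(1), "scheme"),
                   k = vapply(fits, `[[`, numeric(1), "k"),
                   logL = vapply(fits, `[[`, numeric(1), "logL"),
                   AIC = vapply(fits, `[[`, numeric(1), "AIC"),
                   BIC = vapply(fits, `[[`, numeric(1), "BIC"))
  df$dAIC <- df$AIC - min(df$AIC)
  df$dBIC <- df$BIC - min(df$BIC)
  df$rank_aic <- rank(df$AIC, ties.method = "first")
  df$rank_bic <- rank(df$BIC, ties.method = "first")
  df[order(df$AIC), , drop = FALSE]
}

#' Expected outcome for every origin-by-destination cell
#'
#' At covariate reference values (all covariates zero): diagonal cells are
#' `beta0 + delta_k`; off-diagonal cells are
#' `beta0 + p delta_i + (1 - p) delta_j`.
#'
#' @param fit a `drm_fit`, or a list with elements `p`, `delta`, `beta0`
#'   (e.g. generator truth).
#' @return 3 x 3 numeric matrix, origins in rows, destinations in columns.
#' @export
predict_cell_means <- function(fit) {
  p <- fit$p; delta <- fit$delta; beta0 <- fit$beta0
  stopifnot(length(delta) == 3L, abs(sum(delta)) < 1e-8)
  M <- beta0 + p * matrix(delta, 3, 3) + (1 - p) * matrix(delta, 3, 3, byrow = TRUE)
  dimnames(M) <- list(origin = class_levels(), destination = class_levels())
  M
}

#' Export a DRM fit as a report list (for JSON serialization)
#'
#' Mirrors the printed table layout: class effects, weights, covariates,
#' constant, observations, information criteria.
#'
#' @param fit a `drm_fit`.
#' @return nested list of plain numbers suitable for `jsonlite::write_json`.
#' @export
drm_report <- function(fit) {
  stopifnot(inherits(fit, "drm_fit"))
  term_entry <- function(name, est) {
    if (name %in% rownames(fit$ci)) {
      list(estimate = unname(est), se = unname(fit$se[name]),
           ci_lower = unname(fit$ci[name, 1]), ci_upper = unname(fit$ci[name, 2]))
    } else list(estimate = unname(est))
  }
  covs <- lapply(stats::setNames(names(fit$beta), names(fit$beta)),
                 function(nm) term_entry(nm, fit$beta[nm]))
  list(model = fit$model, scheme = fit$scheme,
       class_effects = list(
         disadvantaged = term_entry("delta1", fit$delta[1]),
         intermediate = term_entry("delta2", fit$delta[2]),
         advantaged = list(estimate = unname(fit$delta[3]))),
       origin_weight = term_entry("p", fit$p),
       destination_weight = list(estimate = 1 - fit$p),
       covariates = covs,
       constant = term_entry("beta0", fit$beta0),
       sigma2 = fit$sigma2, logL = fit$logL, AIC = fit$AIC, BIC = fit$BIC,
       n = fit$n, converged = fit$converged, boundary = fit$boundary)
}
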