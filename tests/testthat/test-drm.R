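test_that("design rows combine origin and destination effect codings by p", {
  lv <- class_levels()
  # immobile advantaged person: pure effect coding for any p
  for (p in c(0, 0.3, 1)) {
    M <- build_drm_design(lv[3], lv[3], p)
    expect_equal(unname(M[1, ]), drm_row_oracle(3, 3, p))
    expect_equal(unname(M[1, 2:3]), c(-1, -1))
  }
  # mobile dis -> adv at p = 1 equals an immobile disadvantaged row
  expect_equal(unname(build_drm_design(lv[1], lv[3], 1)[1, ]),
               unname(build_drm_design(lv[1], lv[1], 0.5)[1, ]))
  # mobile dis -> int at p = 0.5: average of the two codings
  expect_equal(unname(build_drm_design(lv[1], lv[2], 0.5)[1, ]),
               drm_row_oracle(1, 2, 0.5))
  expect_equal(drm_row_oracle(1, 2, 0.5), c(1, 0.5, 0.5))
})

test_that("fit at fixed p interpolates noiseless data and matches the OLS oracle", {
  set.seed(20)
  n <- 120
  o <- sample(1:3, n, replace = TRUE)
  d <- sample(1:3, n, replace = TRUE)
  lv <- class_levels()
  delta_true <- c(0.8, -0.2, -0.6)
  x1 <- rnorm(n)
  p_true <- 0.35
  y0 <- 1.5 + p_true * delta_true[o] + (1 - p_true) * delta_true[d] + 0.7 * x1

  # sigma = 0: generating coefficients recovered exactly at p = p_true
  f <- fit_drm_at_p(y0, lv[o], lv[d], p_true, X = cbind(x1 = x1))
  expect_equal(unname(f$delta), delta_true, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["(Intercept)"]), 1.5, tolerance = 1e-8)
  expect_equal(unname(f$coefficients["x1"]), 0.7, tolerance = 1e-8)
  expect_lt(f$sigma2, 1e-16)

  # noisy data: equals the brute-force normal-equations oracle
  y <- y0 + rnorm(n)
  for (p in c(0, 0.25, 0.8)) {
    f2 <- fit_drm_at_p(y, lv[o], lv[d], p, X = cbind(x1 = x1))
    X <- t(vapply(seq_len(n), function(i) drm_row_oracle(o[i], d[i], p),
                  numeric(3)))
    orc <- ols_oracle(cbind(X, x1), y)
    expect_equal(unname(f2$coefficients), unname(orc$beta), tolerance = 1e-8)
    expect_equal(f2$rss, sum(orc$residuals^2), tolerance = 1e-8)
  }

  # balanced equal-cell data at p = 0.5, no covariates: beta0 = grand mean
  ob <- rep(rep(1:3, each = 3), 4); db <- rep(rep(1:3, times = 3), 4)
  yb <- rnorm(length(ob))
  fb <- fit_drm_at_p(yb, lv[ob], lv[db], 0.5)
  expect_equal(unname(fb$coefficients["(Intercept)"]), mean(yb),
               tolerance = 1e-10)

  # logL is monotone decreasing in sigma2 at fixed n
  llof <- function(s2, n) -n / 2 * (log(2 * pi * s2) + 1)
  expect_gt(llof(0.5, 100), llof(1.5, 100))
})

test_that("profile estimator recovers generating parameters", {
  # scaled-up cohort close to the published cell structure
  counts <- round(ukhls_cell_counts() * 5000 / 3140)
  coh <- generate_cohort(cell_counts = counts, p = 0.67,
                         delta = c(0.5, 0, -0.5), sigma = 1, seed = 21)
  f <- fit_drm(coh$y, coh$origin, coh$destination,
               covariates = drm_covs(coh), scheme = "none")
  expect_lt(abs(f$p - 0.67), 0.05)
  expect_true(all(abs(f$delta - c(0.5, 0, -0.5)) < 0.1))
  expect_true(f$converged)
  expect_false(f$boundary)
  # weights sum to one exactly; delta sums to zero by construction
  expect_identical(f$p + f$destination_weight, 1)
  expect_lt(abs(sum(f$delta)), 1e-10)
  # profile grid never beats the refined optimum
  expect_true(all(f$profile$logL <= f$logL + 1e-6))
})

test_that("identifiability and degeneracy are reported, never silent", {
  lv <- class_levels()
  o <- rep(1:3, each = 10)
  y <- rnorm(30)
  expect_error(fit_drm(y, lv[o], lv[o]), "unidentified",
               class = "drmage_validation_error")
  # covariate identical to a mobility dummy -> rank deficiency at inner fit
  set.seed(22)
  o2 <- sample(1:3, 60, replace = TRUE); d2 <- sample(1:3, 60, replace = TRUE)
  mob <- encode_mobility(lv[o2], lv[d2], "any")
  expect_error(
    fit_drm(rnorm(60), lv[o2], lv[d2], covariates = mob, scheme = "any"),
    "aliased", class = "drmage_validation_error")
})

test_that("swapping origin and destination maps p to 1 - p with equal logL", {
  for (seed in c(23, 24)) {
    coh <- generate_cohort(cell_counts = round(ukhls_cell_counts() / 5),
                           p = 0.3, delta = c(1, 0, -1), sigma = 1,
                           seed = seed)
    f1 <- fit_drm(coh$y, coh$origin, coh$destination,
                  covariates = drm_covs(coh), compute_vcov = FALSE)
    f2 <- fit_drm(coh$y, coh$destination, coh$origin,
                  covariates = drm_covs(coh), compute_vcov = FALSE)
    expect_equal(f1$p, 1 - f2$p, tolerance = 1e-4)
    expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
  }
})

test_that("consistent class relabelling permutes delta, leaves p and logL alone", {
  coh <- generate_cohort(cell_counts = round(ukhls_cell_counts() / 5),
                         p = 0.7, delta = c(1, 0, -1), sigma = 1, seed = 25)
  f1 <- fit_drm(coh$y, coh$origin, coh$destination, compute_vcov = FALSE)
  # swap the labels of classes 1 and 2 everywhere (rank order is a naming
  # convention; the likelihood only sees cell membership)
  perm <- c(2L, 1L, 3L)
  lv <- class_levels()
  o2 <- lv[perm[as.integer(coh$origin)]]
  d2 <- lv[perm[as.integer(coh$destination)]]
  f2 <- fit_drm(coh$y, o2, d2, compute_vcov = FALSE)
  expect_equal(f1$logL, f2$logL, tolerance = 1e-6)
  expect_equal(f1$p, f2$p, tolerance = 1e-4)
  expect_equal(unname(f2$delta[perm]), unname(f1$delta), tolerance = 1e-4)
})

test_that("model comparison orders by information criteria and checks inputs", {
  coh <- generate_cohort(cell_counts = round(ukhls_cell_counts() / 5),
                         seed = 26)
  covs <- drm_covs(coh)
  fits <- lapply(c("none", "any"), function(sc)
    fit_drm(coh$y, coh$origin, coh$destination, covariates = covs,
            scheme = sc, compute_vcov = FALSE))
  cmp <- compare_drm(fits)
  expect_equal(nrow(cmp), 2L)
  expect_true(all(diff(cmp$AIC) >= 0))
  expect_equal(min(cmp$dAIC), 0)
  expect_equal(nrow(compare_drm(fits[[1]])), 1L)

  f_other <- fit_drm(coh$y + 1, coh$origin, coh$destination,
                     covariates = covs, compute_vcov = FALSE)
  expect_error(compare_drm(list(fits[[1]], f_other)), "outcome")
  coh2 <- coh[1:100, ]
  f_small <- fit_drm(coh2$y, coh2$origin, coh2$destination,
                     compute_vcov = FALSE)
  expect_error(compare_drm(list(fits[[1]], f_small)), "differing n")
})

test_that("predicted cell means follow the convex-combination formula", {
  mk <- function(p, delta, beta0) list(p = p, delta = delta, beta0 = beta0)
  # p = 1: every row constant at its origin value
  M1 <- predict_cell_means(mk(1, c(1, 0, -1), 0.5))
  for (i in 1:3) expect_true(all(M1[i, ] == M1[i, 1]))
  # hand arithmetic: p = 0.5, delta = (1, 0, -1) -> cell (dis, adv) = 0
  M2 <- predict_cell_means(mk(0.5, c(1, 0, -1), 0))
  expect_equal(M2["disadvantaged", "advantaged"], 0)
  expect_equal(unname(diag(M2)), c(1, 0, -1))
  # diagonal equals beta0 + delta exactly
  M3 <- predict_cell_means(mk(0.37, c(0.4, 0.1, -0.5), 2))
  expect_equal(unname(diag(M3)), 2 + c(0.4, 0.1, -0.5))
})

test_that("fit reports serialize the printed-table layout", {
  coh <- generate_cohort(cell_counts = round(ukhls_cell_counts() / 10),
                         seed = 27)
  f <- fit_drm(coh$y, coh$origin, coh$destination,
               covariates = drm_covs(coh), scheme = "any")
  rep <- drm_report(f)
  expect_named(rep, c("model", "scheme", "class_effects", "origin_weight",
                      "destination_weight", "covariates", "constant",
                      "sigma2", "logL", "AIC", "BIC", "n", "converged",
                      "boundary"))
  expect_equal(rep$origin_weight$estimate + rep$destination_weight$estimate, 1)
  expect_true("mobile" %in% names(rep$covariates))
  expect_output(print(f), "origin weight")
})
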