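test_that("cross-tab means and marginals reduce correctly", {
  lv <- class_levels()
  # all outcomes equal c: every cell mean and marginal equals c
  o <- rep(1:3, each = 6); d <- rep(rep(1:3, each = 2), 3)
  ct <- crosstab_means(rep(2.5, 18), lv[o], lv[d])
  expect_true(all(ct$cell_means == 2.5))
  expect_true(all(ct$row_totals == 2.5) && all(ct$col_totals == 2.5))
  expect_equal(ct$grand, 2.5)

  # two persons in two cells: means equal the individual values; empty
  # cells are NA with n = 0
  ct2 <- crosstab_means(c(1.2, -0.4), lv[c(1, 2)], lv[c(3, 2)])
  expect_equal(ct2$cell_means["disadvantaged", "advantaged"], 1.2)
  expect_equal(ct2$cell_means["intermediate", "intermediate"], -0.4)
  expect_equal(sum(ct2$cell_ns), 2L)
  expect_true(is.na(ct2$cell_means["advantaged", "advantaged"]))

  # marginals from cells agree with person-level marginals
  set.seed(30)
  o3 <- sample(1:3, 200, replace = TRUE); d3 <- sample(1:3, 200, replace = TRUE)
  y3 <- rnorm(200)
  ct3 <- crosstab_means(y3, lv[o3], lv[d3])
  expect_equal(unname(ct3$row_totals), as.numeric(tapply(y3, o3, mean)),
               tolerance = 1e-12)
  expect_equal(unname(ct3$col_totals), as.numeric(tapply(y3, d3, mean)),
               tolerance = 1e-12)
  expect_equal(ct3$grand, mean(y3), tolerance = 1e-12)

  expect_error(marginal_from_cells(matrix(NA_real_, 3, 3),
                                   matrix(1L, 3, 3)), "missing mean")
})

test_that("published marginals reconstruct from published cells and counts", {
  ref <- ukhls_crosstab()
  ns <- ukhls_cell_counts()
  # spot checks printed in the source table
  h <- marginal_from_cells(ref$horvath$cells, ns)
  expect_equal(unname(h$row_totals_2dp["disadvantaged"]), 0.13)
  hn <- marginal_from_cells(ref$hannum$cells, ns)
  expect_equal(unname(hn$col_totals_2dp["disadvantaged"]), 0.05)
})

test_that("group tests use pooled-variance t and one-way ANOVA", {
  # two identical groups: t = 0, p = 1
  g <- rep(c("a", "b"), each = 4)
  y <- rep(c(1, 2, 3, 4), 2)
  r <- group_tests(y, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # hand-computed pooled-variance t on a small fixture
  y1 <- c(4.1, 5.2, 6.0, 5.5); y2 <- c(3.0, 3.8, 4.4)
  sp2 <- (3 * var(y1) + 2 * var(y2)) / 5
  t_hand <- (mean(y1) - mean(y2)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  r2 <- group_tests(c(y1, y2), rep(c("g1", "g2"), c(4, 3)))
  expect_equal(r2$statistic, t_hand, tolerance = 1e-10)
  expect_equal(r2$p_value, 2 * pt(-abs(t_hand), 5), tolerance = 1e-10)

  # three identical groups: F = 0
  r3 <- group_tests(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(r3$method, "anova")
  expect_equal(r3$statistic, 0)

  expect_error(group_tests(1:3, c("a", "a", "b")), "n < 2")
})

test_that("restricted mobile-vs-immobile OLS isolates the group contrast", {
  lv <- class_levels()
  # exact contrast: groups differ by +1, covariates balanced, sigma = 0
  n <- 40
  dat <- data.frame(
    origin = lv[c(rep(3, n / 2), rep(3, n / 2))],
    destination = lv[c(rep(1, n / 2), rep(3, n / 2))],  # downward vs stable adv
    sex = factor(rep(c("male", "female"), n / 2)),
    z_age = rep(c(-1, 1), n / 2))
  dat$z_age2 <- dat$z_age^2
  dat$acceleration <- 1 * (dat$destination == lv[1]) + 0.5 * (dat$sex == "female")
  # a zero-residual fit legitimately triggers lm's perfect-fit warning
  r <- suppressWarnings(
    restricted_mobility_ols(dat, comparison = "down_vs_stable_advantaged"))
  expect_equal(r$estimate, 1.0, tolerance = 1e-10)
  expect_equal(unname(r$ci["lower"]), unname(r$ci["upper"]), tolerance = 1e-8)
  expect_equal(r$n_mobile, n / 2)

  # seeded fixture equals the normal-equations oracle
  set.seed(31)
  coh <- generate_cohort(cell_counts = round(ukhls_cell_counts() / 5),
                         seed = 31)
  coh$acceleration <- coh$y
  r2 <- restricted_mobility_ols(coh, comparison = "up_vs_stable_disadvantaged")
  sel <- with(coh, (as.integer(destination) > as.integer(origin)) |
                (origin == "disadvantaged" & destination == "disadvantaged"))
  sub <- coh[sel, ]
  X <- cbind(1,
             mobile = as.integer(with(sub, as.integer(destination) > as.integer(origin))),
             female = as.integer(sub$sex == "female"),
             sub$z_age, sub$z_age2)
  expect_equal(r2$estimate, unname(ols_oracle(X, sub$acceleration)$beta[2]),
               tolerance = 1e-10)

  # empty mobile group
  stable <- data.frame(origin = lv[3], destination = lv[3], sex = "male",
                       z_age = 0, z_age2 = 0, acceleration = 0)
  expect_error(restricted_mobility_ols(stable,
                                       comparison = "down_vs_stable_advantaged"),
               "empty mobile")
})
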