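test_that("household dominance rule picks the most advantaged member", {
  expect_equal(as.character(household_max_class(c("intermediate", "advantaged"))),
               "advantaged")
  expect_equal(as.character(household_max_class("disadvantaged")),
               "disadvantaged")
  expect_equal(as.character(household_max_class(c("disadvantaged", "disadvantaged"))),
               "disadvantaged")
  expect_equal(as.character(household_max_class(c(NA, "intermediate"))),
               "intermediate")
  expect_true(is.na(household_max_class(c(NA, NA))))
  # order-invariance
  for (pair in list(c("disadvantaged", "advantaged"),
                    c("advantaged", "intermediate"))) {
    expect_equal(household_max_class(pair), household_max_class(rev(pair)))
  }
})

test_that("analytic-sample filter applies the age-25 boundary and completeness", {
  coh <- data.frame(sample_id = paste0("S", 1:5),
                    age = c(24, 25, 40, 30, 35),
                    sex = c("male", "female", "male", "female", NA),
                    origin = class_code(c(1, 1, 2, 2, 3)),
                    destination = class_code(c(2, 3, 2, NA, 1)))
  suppressMessages(out <- filter_analytic_sample(coh))
  expect_equal(out$sample_id, c("S2", "S3"))  # 24 excluded, 25 kept
  ex <- attr(out, "exclusions")
  expect_equal(unname(ex["under_min_age"]), 1L)
  expect_equal(unname(ex["missing_destination"]), 1L)
  expect_equal(unname(ex["missing_sex"]), 1L)

  complete <- data.frame(sample_id = "S1", age = 25, sex = "male",
                         origin = class_code(1), destination = class_code(1))
  suppressMessages(expect_equal(nrow(filter_analytic_sample(complete)), 1L))
  suppressMessages(expect_error(
    filter_analytic_sample(transform(complete, age = 20)), "no rows"))
})

test_that("mobility dummies follow rank arithmetic and sum identities", {
  # dis -> adv, two steps upward
  e <- encode_mobility("disadvantaged", "advantaged", "steps")
  expect_equal(unlist(e), c(up1 = 0L, up2 = 1L, down1 = 0L, down2 = 0L))
  # adv -> int, downward
  e2 <- encode_mobility("advantaged", "intermediate", "direction")
  expect_equal(unlist(e2), c(upward = 0L, downward = 1L))
  # immobile: all dummies zero in every scheme
  for (sc in c("any", "direction", "steps")) {
    e3 <- encode_mobility("intermediate", "intermediate", sc)
    expect_true(all(unlist(e3) == 0L))
  }
  expect_equal(ncol(encode_mobility("disadvantaged", "advantaged", "none")), 0L)

  # properties over all 9 origin-destination pairs
  grid <- expand.grid(o = 1:3, d = 1:3)
  any_ <- encode_mobility(grid$o, grid$d, "any")
  dir_ <- encode_mobility(grid$o, grid$d, "direction")
  stp_ <- encode_mobility(grid$o, grid$d, "steps")
  expect_equal(dir_$upward + dir_$downward, any_$mobile)
  expect_equal(stp_$up1 + stp_$up2, dir_$upward)
  expect_equal(stp_$down1 + stp_$down2, dir_$downward)
  expect_true(all(rowSums(stp_) <= 1))
})

test_that("age standardization uses the n-1 SD and squares afterwards", {
  coh <- data.frame(age = c(50, 60))
  out <- standardize_covariates(coh)
  expect_equal(out$z_age, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(out$z_age2, out$z_age^2)

  set.seed(13)
  coh2 <- data.frame(age = runif(40, 25, 90))
  out2 <- standardize_covariates(coh2)
  expect_lt(abs(mean(out2$z_age)), 1e-12)
  expect_equal(sd(out2$z_age), 1, tolerance = 1e-12)

  expect_error(standardize_covariates(data.frame(age = rep(50, 3))),
               "distinct ages")
})

test_that("birth-cohort split re-standardizes within stratum", {
  coh <- data.frame(age = c(70, 68, 40, 35, 30),
                    birth_year = c(1941, 1943, 1956, 1976, 1981))
  st <- split_birth_cohort(coh, cutoff = 1956)
  expect_equal(nrow(st$old), 2L)     # born 1956 goes young by default
  expect_equal(nrow(st$young), 3L)
  expect_lt(abs(mean(st$young$z_age)), 1e-12)
  st2 <- split_birth_cohort(coh, cutoff = 1956, young_includes_cutoff = FALSE)
  expect_equal(nrow(st2$old), 3L)
})
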