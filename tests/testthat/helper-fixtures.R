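# shared test fixtures, built in code

write_clock_file <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("probe,coefficient",
               vapply(rows, function(r) paste(r[[1]], r[[2]], sep = ","),
                      character(1))),
             path)
  path
}

# tiny beta matrix with the probes/values of the worked clock example
example_betas <- function() {
  m <- matrix(c(0.5, 0.2, 0.8), nrow = 3,
              dimnames = list(c("cgA", "cgB", "cgC"), "S1"))
  m
}

example_clock <- function() {
  clock_definition(c(cgA = 2, cgB = -1, cgC = 0.5), intercept = 10,
                   name = "example")
}

# brute-force OLS oracle via explicit normal equations
ols_oracle <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(beta = drop(beta), residuals = y - drop(X %*% beta))
}

# independently constructed DRM design row (hand effect coding)
drm_row_oracle <- function(o, d, p) {
  ec <- list(c(1, 0), c(0, 1), c(-1, -1))
  c(1, p * ec[[o]] + (1 - p) * ec[[d]])
}

drm_covs <- function(cohort) cohort[, c("sex", "z_age", "z_age2")]
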