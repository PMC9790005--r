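# Reference-based cell-type deconvolution (Houseman-style constrained
# projection): per sample, the cell fractions w minimize ||b - R w||^2
# subject to w >= 0 and sum(w) <= 1, where R holds the reference beta means
# on the probes shared between the sample matrix and the reference.
#
# The problem is a small convex QP (K cell types, K typically 3-7). It is
# solved exactly by enumerating candidate active sets: for every subset of
# zeroed fractions, with the sum constraint either slack or tight, the
# equality-constrained least-squares stationary point is computed in closed
# form; the feasible candidate with the smallest objective is the global
# optimum. Because R is fixed across samples, each candidate's solve
# operator is precomputed once and applied to all samples at once.

#' Read a cell-type reference profile
#'
#' Delimited text (comma or tab, auto-detected), first column CpG probe ID,
#' one column of reference beta means per cell type.
#'
#' @param path path to the file.
#' @return numeric matrix, probes x cell types, values in \[0, 1\].
#' @export
read_cell_reference <- function(path) {
  if (!file.exists(path)) stop_validation("reference file not found: ", path)
  delim <- detect_delim(path)
  tab <- utils::read.table(path, header = TRUE, sep = delim,
                           check.names = FALSE, row.names = 1L)
  R <- as.matrix(tab)
  storage.mode(R) <- "double"
  if (any(R < 0 | R > 1, na.rm = TRUE)) {
    stop_validation("reference profile values must lie in [0, 1]")
  }
  R
}

#' Estimate white blood cell fractions by constrained projection
#'
#' For each sample solves `min ||b - R w||^2` subject to `w >= 0` and
#' `sum(w) <= 1` on the probes shared between `betas` and `reference`.
#'
#' @param betas probes x samples beta matrix.
#' @param reference probes x cell-types matrix of reference beta means
#'   (see [read_cell_reference()]).
#' @return object of class `cell_fractions`: samples x cell-types matrix of
#'   estimated fractions, with attributes `n_probes` (shared probes used)
#'   and `objective` (per-sample residual sum of squares).
#' @export
estimate_cell_fractions <- function(betas, reference) {
  validate_beta_matrix(betas)
  K <- ncol(reference)
  shared <- intersect(rownames(betas), rownames(reference))
  if (length(shared) < K) {
    stop_validation(sprintf(
      "only %d probe(s) shared between betas and reference; need at least %d",
      length(shared), K))
  }
  R <- reference[shared, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < K) {
    aliased <- colnames(R)[qrR$pivot[(qrR$rank + 1L):K]]
    stop_validation("reference columns collinear on shared probes: ",
                    paste(aliased, collapse = ", "))
  }
  B <- betas[shared, , drop = FALSE]
  if (anyNA(B)) stop_validation("NA beta values on reference probes")
  n <- ncol(B)
  G <- crossprod(R)            # K x K
  RtB <- crossprod(R, B)       # K x n
  bss <- colSums(B^2)

  best_obj <- rep(Inf, n)
  W <- matrix(0, K, n)
  ones <- rep(1, K)

  for (mask in 0:(2^K - 1L)) {
    free <- which(bitwAnd(mask, 2^(0:(K - 1L))) == 0L)
    kf <- length(free)
    for (sum_tight in c(FALSE, TRUE)) {
      if (kf == 0L) {
        if (sum_tight) next  # sum(w)=1 with all w=0 is infeasible
        cand <- matrix(0, K, n)
      } else {
        Gf <- G[free, free, drop = FALSE]
        if (sum_tight) {
          A <- rbind(cbind(Gf, ones[seq_len(kf)]),
                     c(ones[seq_len(kf)], 0))
          rhs <- rbind(RtB[free, , drop = FALSE], rep(1, n))
          sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
          if (is.null(sol)) next
          wf <- sol[seq_len(kf), , drop = FALSE]
        } else {
          wf <- tryCatch(solve(Gf, RtB[free, , drop = FALSE]),
                         error = function(e) NULL)
          if (is.null(wf)) next
        }
        cand <- matrix(0, K, n)
        cand[free, ] <- wf
      }
      feas <- colSums(cand < -1e-9) == 0L & colSums(cand) <= 1 + 1e-9
      if (!any(feas)) next
      obj <- bss - 2 * colSums(cand * RtB) + colSums(cand * (G %*% cand))
      take <- feas & obj < best_obj - 1e-12
      if (any(take)) {
        W[, take] <- cand[, take, drop = FALSE]
        best_obj[take] <- obj[take]
      }
    }
  }
  W[W < 0 & W > -1e-9] <- 0  # clamp active-set round-off
  out <- t(W)
  dimnames(out) <- list(colnames(betas), colnames(reference))
  stopifnot(all(out >= -1e-8), all(rowSums(out) <= 1 + 1e-6))
  structure(out, class = c("cell_fractions", "matrix", "array"),
            n_probes = length(shared), objective = best_obj)
}
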