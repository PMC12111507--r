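check_beta <- function(beta, what = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("'", what, "' must be a numeric matrix (CpGs x samples)")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'", what, "' must carry CpG rownames and sample colnames")
  if (anyDuplicated(rownames(beta))) stop("duplicate CpG ids in '", what, "'")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids in '", what, "'")
  if (anyNA(beta)) stop("missing values in '", what, "'")
  invisible(beta)
}

#' Beta to M-value transform
#'
#' `M = log2((beta + offset) / (1 - beta + offset))`, the log odds of
#' methylation. A small `offset` keeps boundary values finite; the default
#' 1e-6 leaves mid-range values unchanged to ~1e-5.
#'
#' @param beta CpG x sample matrix of methylation fractions in \[0,1\].
#' @param offset nonnegative stabilising fraction, at most 0.01.
#' @return matrix of M-values with the same dimnames.
#' @export
beta_to_m <- function(beta, offset = 1e-6) {
  check_beta(beta)
  if (offset < 0 || offset > 0.01) stop("'offset' must lie in [0, 0.01]")
  if (any(beta < 0 | beta > 1))
    stop("beta values outside [0, 1]")
  log2((beta + offset) / (1 - beta + offset))
}

#' Inverse of [beta_to_m()] at offset zero
#'
#' @param m matrix of M-values.
#' @return matrix of beta values, `2^m / (1 + 2^m)`.
#' @export
m_to_beta <- function(m) {
  e <- 2^m
  e / (1 + e)
}

#' Remove CpGs with low variability across samples
#'
#' @param beta CpG x sample beta matrix with at least two samples.
#' @param sd_threshold retain rows whose across-sample SD is at least this
#'   value (beta scale). Default 0.01.
#' @return list with `beta` (retained rows, order preserved) and `removed`
#'   (dropped CpG ids).
#' @export
filter_low_variability <- function(beta, sd_threshold = 0.01) {
  check_beta(beta)
  if (ncol(beta) < 2L) stop("SD is undefined with a single sample")
  if (sd_threshold < 0) stop("'sd_threshold' must be >= 0")
  sds <- apply(beta, 1L, stats::sd)
  keep <- sds >= sd_threshold
  list(beta = beta[keep, , drop = FALSE], removed = rownames(beta)[!keep])
}

#' Drop blacklisted CpGs (e.g. SNP-overlapping probes)
#'
#' Ids absent from the matrix are ignored with a message; row order of the
#' survivors is preserved.
#'
#' @param beta CpG x sample beta matrix.
#' @param blacklist character vector of CpG ids to drop.
#' @return the filtered beta matrix.
#' @export
exclude_blacklist <- function(beta, blacklist) {
  check_beta(beta)
  absent <- setdiff(blacklist, rownames(beta))
  if (length(absent))
    message(length(absent), " blacklist id(s) not present in the matrix; ignored")
  out <- beta[!rownames(beta) %in% blacklist, , drop = FALSE]
  if (nrow(out) == 0L) warning("blacklist removed every CpG")
  out
}

#' Estimate surrogate variables (residual-space PCA with full-data scoring)
#'
#' Latent batch directions are identified as the first `k` principal
#' components of the sample-space residuals after removing the
#' primary-variable group means from each CpG. Per-CpG loadings on those
#' directions are then used to re-score the samples on the full
#' (row-centred) data by least squares, so the surrogate variables retain
#' any component of the batch structure that is incidentally correlated
#' with the primary variable — pure residual PCA is orthogonal to the
#' primary variable by construction and would leave exactly that
#' confounded component uncorrected. Columns are mutually orthogonal with
#' zero mean and unit sample variance; their sign is arbitrary.
#'
#' @param m CpG x sample matrix (M-values by default in the pipeline).
#' @param primary factor/vector of the primary variable (e.g. case-control
#'   group), one entry per sample.
#' @param k number of surrogate variables, `0 < k < n_samples - 2`.
#' @return sample x k matrix with columns `SV1..SVk`.
#' @export
estimate_sv <- function(m, primary, k = 5L) {
  check_beta(m, "m")
  n <- ncol(m)
  if (length(primary) != n) stop("'primary' must have one entry per sample")
  if (k <= 0L) stop("'k' must be positive")
  if (k >= n - 2L) stop("'k' must be < n_samples - 2")
  g <- as.factor(primary)
  resid <- m
  for (lev in levels(g)) {
    i <- which(g == lev)
    resid[, i] <- m[, i, drop = FALSE] - rowMeans(m[, i, drop = FALSE])
  }
  v <- svd(resid, nu = 0, nv = k)$v[, seq_len(k), drop = FALSE]
  loadings <- resid %*% v
  centred <- m - rowMeans(m)
  sv <- crossprod(centred, loadings) %*% solve(crossprod(loadings))
  sv <- qr.Q(qr(sv))
  sv <- sweep(sv, 2L, apply(sv, 2L, stats::sd), "/")
  dimnames(sv) <- list(colnames(m), paste0("SV", seq_len(k)))
  sv
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor `j` on the others.
#' Exactly collinear predictors are reported as `Inf` with a warning rather
#' than silently dropped.
#'
#' @param design numeric sample x predictor matrix with column names, at
#'   least two predictors and more samples than predictors.
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  if (!is.matrix(design)) design <- as.matrix(design)
  if (ncol(design) < 2L) stop("need at least two predictors")
  if (nrow(design) <= ncol(design)) stop("need more samples than predictors")
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))
  out <- stats::setNames(numeric(ncol(design)), colnames(design))
  for (j in seq_len(ncol(design))) {
    fit <- stats::lm.fit(cbind(1, design[, -j, drop = FALSE]), design[, j])
    tss <- sum((design[, j] - mean(design[, j]))^2)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(out)))
    warning("exactly collinear predictors: ",
            paste(names(out)[!is.finite(out)], collapse = ", "))
  out
}
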