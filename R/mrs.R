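#' Stratify CpGs by EWAS p-value thresholds
#'
#' Selects, for each cutoff, the CpGs with `p < threshold` (strict). The
#' default thresholds are the conventional six-decade ladder 1e-6 ... 1e-1,
#' and the resulting sets are nested by construction.
#'
#' @param fit an [ewas()] object.
#' @param thresholds increasing p-value cutoffs in (0, 1).
#' @return named list (one element per threshold, formatted like `"1e-05"`)
#'   of CpG id character vectors. Empty sets are allowed and messaged.
#' @export
stratify_cpgs <- function(fit, thresholds = 10^(-6:-1)) {
  stopifnot(inherits(fit, "ewas"))
  r <- fit$results[!is.na(fit$results$p), ]
  if (nrow(r) == 0L) stop("EWAS result carries no usable p-values")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must be in (0,1)")
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be strictly increasing")
  sets <- lapply(thresholds, function(th) r$cpg[r$p < th])
  names(sets) <- format(thresholds, scientific = TRUE, trim = TRUE)
  empty <- vapply(sets, length, 1L) == 0L
  if (any(empty))
    message("empty CpG set at threshold(s): ", paste(names(sets)[empty], collapse = ", "))
  sets
}

#' Raw methylation risk score
#'
#' Per-sample weighted sum `score_s = sum_i M_is * Z_i` over the selected
#' CpG set, where `Z_i = effect_i / se_i` is the EWAS Wald statistic. The
#' conventional score uses M-values; pass a beta matrix to `m` for a
#' scale-consistent variant.
#'
#' @param m CpG x sample matrix of M-values (or betas).
#' @param fit the [ewas()] object supplying the weights.
#' @param cpg_ids CpG set (one element of [stratify_cpgs()]).
#' @return named numeric vector of raw scores, one per sample.
#' @export
compute_mrs <- function(m, fit, cpg_ids) {
  stopifnot(inherits(fit, "ewas"))
  if (length(cpg_ids) == 0L)
    return(stats::setNames(rep(0, ncol(m)), colnames(m)))
  miss <- setdiff(cpg_ids, rownames(m))
  if (length(miss))
    stop("CpG(s) missing from the matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  miss2 <- setdiff(cpg_ids, fit$results$cpg)
  if (length(miss2))
    stop("CpG(s) missing from the EWAS result: ", paste(utils::head(miss2, 5), collapse = ", "))
  z <- with(fit$results, stats::setNames(effect / se, cpg))[cpg_ids]
  colSums(m[cpg_ids, , drop = FALSE] * z)
}

#' Z-score a vector of raw risk scores
#'
#' `(x - mean(x)) / sd(x)` with the sample (n-1) standard deviation.
#'
#' @param raw numeric vector of at least two raw scores.
#' @param label optional label (e.g. the threshold) used in error messages.
#' @return z-scores with mean 0 and SD 1.
#' @export
zscore_mrs <- function(raw, label = NULL) {
  if (length(raw) < 2L) stop("need at least two samples")
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop("zero variance in raw scores",
         if (!is.null(label)) paste0(" at threshold ", label) else "")
  (raw - mean(raw)) / s
}

#' Threshold-stratified methylation risk score profile
#'
#' Computes raw and z-scored risk scores at every p-value threshold.
#'
#' @param m CpG x sample M-value matrix.
#' @param fit the [ewas()] object.
#' @param thresholds increasing p-value cutoffs; default six decades
#'   1e-6 ... 1e-1.
#' @return object of class `mrs_profile`: list with `scores` (long
#'   data.frame: `sample_id`, `threshold`, `raw`, `z`), `n_cpgs` (named
#'   integer per threshold) and `sets` (the CpG sets used).
#' @export
mrs_profile <- function(m, fit, thresholds = 10^(-6:-1)) {
  sets <- stratify_cpgs(fit, thresholds)
  nonempty <- names(sets)[vapply(sets, length, 1L) > 0L]
  rows <- lapply(names(sets), function(th) {
    raw <- compute_mrs(m, fit, sets[[th]])
    z <- if (length(sets[[th]]) > 0L) zscore_mrs(raw, th) else rep(NA_real_, length(raw))
    data.frame(sample_id = colnames(m), threshold = th, raw = as.numeric(raw),
               z = as.numeric(z), stringsAsFactors = FALSE)
  })
  structure(list(scores = do.call(rbind, rows),
                 n_cpgs = vapply(sets, length, 1L),
                 sets = sets, thresholds = thresholds),
            class = "mrs_profile")
}

#' @export
print.mrs_profile <- function(x, ...) {
  cat("Methylation risk score profile\n")
  for (th in names(x$n_cpgs))
    cat(sprintf("  p < %-7s: %d CpGs\n", th, x$n_cpgs[[th]]))
  invisible(x)
}

# Firth-penalized logistic regression (Jeffreys prior), used as the
# documented fallback when ordinary ML separates on small cohorts.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- p * (1 - p)
    XtWX <- crossprod(X * W, X)
    inv <- solve(XtWX)
    h <- rowSums((X %*% inv) * (X * W))
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  W <- stats::plogis(eta) * (1 - stats::plogis(eta))
  se <- sqrt(diag(solve(crossprod(X * W, X))))
  list(coefficients = beta, se = se)
}

#' Associate the methylation risk score with a phenotype
#'
#' Regresses the phenotype on the z-scored risk score at each threshold.
#' With `family = "auto"` a two-valued phenotype is fit by logistic
#' regression and anything else by ordinary least squares. Logistic fits
#' that separate (fitted probabilities at 0/1) are refit with
#' Firth-penalized likelihood and flagged `"firth"` rather than reported
#' silently.
#'
#' @param profile an [mrs_profile()] object.
#' @param sheet sample sheet data.frame with a `sample_id` column.
#' @param phenotype name of the response column in `sheet`.
#' @param family `"auto"`, `"linear"` or `"logistic"`.
#' @return data.frame per threshold: `threshold`, `n_cpgs`, `beta`,
#'   `ci_lo`, `ci_hi`, `p`, `family`, `significant`, `flag` — the shape of
#'   a forest plot.
#' @export
associate_mrs <- function(profile, sheet, phenotype,
                          family = c("auto", "linear", "logistic")) {
  stopifnot(inherits(profile, "mrs_profile"))
  family <- match.arg(family)
  if (!phenotype %in% names(sheet)) stop("phenotype '", phenotype, "' not in sheet")
  y_all <- sheet[[phenotype]][match(unique(profile$scores$sample_id), sheet$sample_id)]
  if (anyNA(y_all)) stop("missing phenotype values")
  if (length(y_all) < 8L) stop("need at least 8 samples")
  if (family == "auto")
    family <- if (length(unique(y_all)) == 2L) "logistic" else "linear"
  if (family == "logistic") {
    yl <- as.numeric(factor(y_all)) - 1
    if (length(unique(yl)) < 2L) stop("binary phenotype has a single class")
  }
  out <- lapply(names(profile$n_cpgs), function(th) {
    sc <- profile$scores[profile$scores$threshold == th, ]
    z <- sc$z[match(unique(profile$scores$sample_id), sc$sample_id)]
    row <- data.frame(threshold = th, n_cpgs = profile$n_cpgs[[th]],
                      beta = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      p = NA_real_, family = family, significant = NA,
                      flag = "", stringsAsFactors = FALSE)
    if (all(is.na(z))) { row$flag <- "empty_set"; return(row) }
    if (family == "linear") {
      fit <- stats::lm(y_all ~ z)
      cf <- summary(fit)$coefficients["z", ]
      ci <- stats::confint(fit)["z", ]
      row$beta <- cf["Estimate"]; row$p <- cf["Pr(>|t|)"]
      row$ci_lo <- ci[1]; row$ci_hi <- ci[2]
    } else {
      yl <- as.numeric(factor(y_all)) - 1
      X <- cbind(1, z)
      fit <- suppressWarnings(stats::glm(yl ~ z, family = stats::binomial()))
      sep <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8) ||
        !fit$converged || abs(stats::coef(fit)["z"]) > 20
      if (sep) {
        ff <- firth_logistic(X, yl)
        row$beta <- ff$coefficients[2]
        se <- ff$se[2]
        row$flag <- "separation_firth"
      } else {
        cf <- summary(fit)$coefficients["z", ]
        row$beta <- cf["Estimate"]; se <- cf["Std. Error"]
      }
      row$ci_lo <- row$beta - 1.959964 * se
      row$ci_hi <- row$beta + 1.959964 * se
      row$p <- 2 * stats::pnorm(-abs(row$beta / se))
    }
    row$significant <- row$p < 0.05
    row
  })
  do.call(rbind, out)
}
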