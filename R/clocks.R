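#' Construct a linear epigenetic clock
#'
#' A clock is an intercept plus CpG weights applied to beta values,
#' optionally followed by the inverse of the Horvath age transform. Units
#' distinguish ordinary age clocks (`"years"`) from telomere-length
#' (`"kilobases"`) and pace-of-aging (`"rate"`) estimators, which always
#' use the identity transform.
#'
#' @param name clock name.
#' @param intercept numeric intercept.
#' @param weights named numeric vector of CpG weights (may be empty for an
#'   intercept-only clock).
#' @param transform `"identity"` or `"horvath"`.
#' @param adult_age anchor age (years) for the Horvath transform; required
#'   and positive when `transform = "horvath"`.
#' @param units `"years"`, `"kilobases"` or `"rate"`.
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, weights = numeric(0),
                        transform = c("identity", "horvath"),
                        adult_age = NULL, units = c("years", "kilobases", "rate")) {
  transform <- match.arg(transform)
  units <- match.arg(units)
  if (!is.numeric(intercept) || length(intercept) != 1L || !is.finite(intercept))
    stop("'intercept' must be a finite scalar")
  if (length(weights) && (is.null(names(weights)) || anyDuplicated(names(weights))))
    stop("'weights' must be uniquely named by CpG id")
  if (transform == "horvath") {
    if (is.null(adult_age) || adult_age <= 0)
      stop("horvath transform requires adult_age > 0")
  } else adult_age <- NULL
  structure(list(name = name, intercept = intercept, weights = weights,
                 transform = transform, adult_age = adult_age, units = units),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Epigenetic clock '%s': %d CpG weight(s), transform %s%s, units %s\n",
              x$name, length(x$weights), x$transform,
              if (x$transform == "horvath") sprintf("(%g)", x$adult_age) else "",
              x$units))
  invisible(x)
}

#' Horvath age transform (forward)
#'
#' Maps chronological age to the transformed scale clocks are trained on:
#' `log((age + 1)/(adult_age + 1))` below `adult_age`, linear
#' `(age - adult_age)/(adult_age + 1)` above. Continuous and strictly
#' increasing.
#'
#' @param age age in years (> -1).
#' @param adult_age anchor age in years.
#' @return transformed value.
#' @export
horvath_forward <- function(age, adult_age = 20) {
  ifelse(age < adult_age, log((age + 1) / (adult_age + 1)),
         (age - adult_age) / (adult_age + 1))
}

#' Horvath age transform (inverse)
#'
#' @param x transformed value (finite).
#' @param adult_age anchor age in years.
#' @return age in years: `(adult_age + 1) * exp(x) - 1` for `x < 0`,
#'   `x * (adult_age + 1) + adult_age` for `x >= 0`.
#' @export
horvath_inverse <- function(x, adult_age = 20) {
  if (any(!is.finite(x))) stop("'x' must be finite")
  ifelse(x < 0, (adult_age + 1) * exp(x) - 1, x * (adult_age + 1) + adult_age)
}

#' Apply an epigenetic clock to a beta matrix
#'
#' Computes `raw_s = intercept + sum_i w_i beta_is` per sample and back-maps
#' through the clock's inverse transform. Clock CpGs absent from the matrix
#' abort under the `"error"` policy (the ids are listed); under
#' `"mean_impute"` each missing CpG is filled with the mean beta of the
#' clock CpGs that are present in that sample (0.5 when none are).
#'
#' @param beta CpG x sample beta matrix.
#' @param model a [clock_model()].
#' @param missing_policy `"error"` or `"mean_impute"`.
#' @param min_coverage minimum fraction of clock CpGs that must be present
#'   (default 1 under the error policy).
#' @return named numeric vector of per-sample estimates in the clock's
#'   units.
#' @export
apply_clock <- function(beta, model, missing_policy = c("error", "mean_impute"),
                        min_coverage = NULL) {
  stopifnot(inherits(model, "clock_model"))
  missing_policy <- match.arg(missing_policy)
  check_beta(beta)
  ids <- names(model$weights)
  present <- intersect(ids, rownames(beta))
  if (is.null(min_coverage)) min_coverage <- if (missing_policy == "error") 1 else 0.5
  if (length(ids)) {
    cov <- length(present) / length(ids)
    miss <- setdiff(ids, present)
    if (length(miss) && missing_policy == "error")
      stop("clock CpG(s) missing from matrix: ",
           paste(utils::head(miss, 10), collapse = ", "),
           if (length(miss) > 10) sprintf(" ... (%d total)", length(miss)) else "")
    if (cov < min_coverage)
      stop(sprintf("clock CpG coverage %.2f below minimum %.2f", cov, min_coverage))
  }
  raw <- rep(model$intercept, ncol(beta))
  names(raw) <- colnames(beta)
  if (length(present))
    raw <- raw + colSums(beta[present, , drop = FALSE] * model$weights[present])
  if (length(ids) > length(present)) {
    fill <- if (length(present)) colMeans(beta[present, , drop = FALSE]) else rep(0.5, ncol(beta))
    raw <- raw + fill * sum(model$weights[setdiff(ids, present)])
  }
  if (model$transform == "horvath") horvath_inverse(raw, model$adult_age) else raw
}

#' @export
predict.clock_model <- function(object, beta, ...) apply_clock(beta, object, ...)

#' Epigenetic age acceleration
#'
#' Residuals of the least-squares regression of epigenetic age on
#' chronological age; positive values mark faster-than-expected agers.
#'
#' @param epiage per-sample epigenetic age estimates.
#' @param chronage per-sample chronological ages (non-constant, >= 3
#'   samples).
#' @return residual vector with mean zero.
#' @export
age_acceleration <- function(epiage, chronage) {
  if (length(epiage) != length(chronage)) stop("length mismatch")
  if (length(epiage) < 3L) stop("need at least 3 samples")
  if (stats::sd(chronage) == 0) stop("chronological age is constant")
  stats::residuals(stats::lm(epiage ~ chronage))
}

#' Correlate clock estimates with numeric traits
#'
#' For every (clock, trait) pair computes a correlation and two-sided
#' p-value, choosing Pearson when both variables pass a Shapiro-Wilk
#' normality screen at alpha = 0.05 and Spearman otherwise, and recording
#' the method used. Constant traits are flagged, not fatal.
#'
#' @param ages data.frame or matrix of per-sample clock estimates (samples
#'   in rows, one column per clock), or a named vector for a single clock.
#' @param sheet sample sheet with the trait columns, same sample order.
#' @param traits character vector of numeric trait names.
#' @return data.frame: `clock`, `trait`, `r`, `p`, `method`, `n`, `flag`.
#' @export
clock_trait_cor <- function(ages, sheet, traits) {
  if (is.null(dim(ages))) ages <- data.frame(clock = ages)
  ages <- as.data.frame(ages)
  missing_tr <- setdiff(traits, names(sheet))
  if (length(missing_tr)) stop("trait(s) not in sheet: ", paste(missing_tr, collapse = ", "))
  rows <- list()
  for (cl in names(ages)) for (tr in traits) {
    x <- ages[[cl]]; y <- as.numeric(sheet[[tr]])
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    row <- data.frame(clock = cl, trait = tr, r = NA_real_, p = NA_real_,
                      method = NA_character_, n = length(x), flag = "",
                      stringsAsFactors = FALSE)
    if (length(x) < 4L) { row$flag <- "too_few_pairs" }
    else if (stats::sd(x) == 0 || stats::sd(y) == 0) { row$flag <- "constant" }
    else {
      normal <- function(v) {
        if (length(unique(v)) < 3L) return(FALSE)
        stats::shapiro.test(v)$p.value >= 0.05
      }
      method <- if (normal(x) && normal(y)) "pearson" else "spearman"
      ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
      row$r <- unname(ct$estimate); row$p <- ct$p.value; row$method <- method
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Stepwise regression of epigenetic age on candidate predictors
#'
#' Bidirectional stepwise selection (default AIC) starting from the
#' intercept-only model, as commonly used to relate clock output to
#' sociodemographic and clinical variables. Returns the retained terms
#' with coefficient, SE, 95% confidence interval (`estimate +/-
#' t(0.975, df) * SE`) and p-value.
#'
#' @param epiage per-sample epigenetic ages (response).
#' @param sheet sample sheet containing the candidate columns.
#' @param candidates nonempty character vector of candidate predictor
#'   names; `n` must exceed `length(candidates) + 2`.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return list with `terms` (data.frame: `term`, `estimate`, `se`,
#'   `ci_lo`, `ci_hi`, `p`) and the fitted `model`.
#' @export
stepwise_clock_regression <- function(epiage, sheet, candidates,
                                      criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (length(candidates) == 0L) stop("empty candidate set")
  missing_c <- setdiff(candidates, names(sheet))
  if (length(missing_c)) stop("candidate(s) not in sheet: ", paste(missing_c, collapse = ", "))
  n <- length(epiage)
  if (n <= length(candidates) + 2L) stop("too few samples for the candidate set")
  dat <- data.frame(.epiage = epiage, sheet[candidates], check.names = FALSE)
  X <- as.matrix(dat[candidates])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("perfect collinearity among candidates")
  k <- if (criterion == "AIC") 2 else log(n)
  scope <- stats::reformulate(candidates)
  fit0 <- stats::lm(.epiage ~ 1, data = dat)
  fit <- stats::step(fit0, scope = list(lower = ~1, upper = scope),
                     direction = "both", k = k, trace = 0)
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  tcrit <- stats::qt(0.975, df)
  terms <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      ci_lo = sm[, 1] - tcrit * sm[, 2],
                      ci_hi = sm[, 1] + tcrit * sm[, 2],
                      p = sm[, 4], stringsAsFactors = FALSE, row.names = NULL)
  list(terms = terms, model = fit,
       selected = setdiff(terms$term, "(Intercept)"))
}
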