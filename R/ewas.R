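#' Epigenome-wide association of methylation with case status
#'
#' Fits one association model per CpG. In the default
#' `"meth_outcome"` mode the methylation value (beta or M) is regressed on
#' group plus covariates by ordinary least squares and the group
#' coefficient is reported, so on the beta scale the effect is the adjusted
#' case-minus-control methylation difference; two-sided p-values come from
#' the Student t reference with `df = n - p` (appropriate for small
#' cohorts). In `"logistic"` mode case status is the response and the CpG
#' value the predictor of interest, and the CpG coefficient with its Wald z
#' p-value is reported.
#'
#' Constant CpG rows cannot be tested in the default mode; they are flagged
#' (`flag = "constant"`) and their statistics set to `NA` rather than
#' aborting the scan.
#'
#' @param meth CpG x sample matrix (beta values or M-values).
#' @param group factor or vector with two levels; the second level (or
#'   `"case"` when present) is treated as the case group.
#' @param covariates optional sample x p numeric matrix (e.g. age, sex and
#'   surrogate variables). Checked for multicollinearity with [vif()].
#' @param mode `"meth_outcome"` (default) or `"logistic"`.
#' @return An object of class `ewas`: a list with `results` (data.frame
#'   with columns `cpg`, `effect`, `se`, `t`, `p`, `df`, `flag`), the
#'   model metadata, and the genomic-inflation factor accessible through
#'   [summary.ewas()].
#' @examples
#' cohort <- simulate_cohort(sim_config(n_cpgs = 200, n_causal = 5, seed = 3))
#' fit <- ewas(cohort$beta, cohort$samples$group,
#'             covariates = cbind(age = cohort$samples$age, sex = cohort$samples$sex))
#' summary(fit)
#' @export
ewas <- function(meth, group, covariates = NULL,
                 mode = c("meth_outcome", "logistic")) {
  mode <- match.arg(mode)
  check_beta(meth, "meth")
  n <- ncol(meth)
  if (length(group) != n) stop("'group' must have one entry per sample")
  if (anyNA(group)) stop("missing values in 'group'")
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("'group' must have exactly two levels")
  case_level <- if ("case" %in% levels(g)) "case" else levels(g)[2L]
  y01 <- as.numeric(g == case_level)

  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("'covariates' must have one row per sample")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    if (ncol(covariates) >= 2L) {
      v <- vif(covariates)
      if (any(!is.finite(v))) stop("collinear covariates; see vif()")
    }
  }
  p_model <- 2L + if (is.null(covariates)) 0L else ncol(covariates)
  if (n < p_model + 1L) stop("too few samples for the model (need >= p + 3)")

  flag <- rep("", nrow(meth))
  const <- apply(meth, 1L, function(r) max(r) - min(r) == 0)
  flag[const] <- "constant"

  if (mode == "meth_outcome") {
    X <- cbind(`(Intercept)` = 1, group = y01, covariates)
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
    df <- n - ncol(X)
    fit <- stats::lm.fit(X, t(meth))
    coefs <- fit$coefficients
    res <- fit$residuals                      # n x n_cpg
    rss <- colSums(res^2)
    sigma2 <- rss / df
    xtx_inv_gg <- solve(crossprod(X))["group", "group"]
    eff <- coefs["group", ]
    se <- sqrt(sigma2 * xtx_inv_gg)
    tt <- eff / se
    pp <- 2 * stats::pt(-abs(tt), df)
    out <- data.frame(cpg = rownames(meth), effect = as.numeric(eff),
                      se = as.numeric(se), t = as.numeric(tt),
                      p = as.numeric(pp), df = df, flag = flag,
                      stringsAsFactors = FALSE, row.names = NULL)
    out[const, c("effect", "se", "t", "p")] <- NA_real_
  } else {
    Xbase <- cbind(`(Intercept)` = 1, cpg = 0, covariates)
    df <- n - ncol(Xbase)
    out <- data.frame(cpg = rownames(meth), effect = NA_real_, se = NA_real_,
                      t = NA_real_, p = NA_real_, df = df, flag = flag,
                      stringsAsFactors = FALSE, row.names = NULL)
    for (i in seq_len(nrow(meth))) {
      if (const[i]) next
      Xi <- Xbase; Xi[, "cpg"] <- meth[i, ]
      fit <- suppressWarnings(stats::glm.fit(Xi, y01, family = stats::binomial()))
      sm <- chol2inv(chol(crossprod(Xi * sqrt(fit$weights))))
      eff <- fit$coefficients["cpg"]
      se <- sqrt(sm[2L, 2L])
      out$effect[i] <- eff; out$se[i] <- se; out$t[i] <- eff / se
      out$p[i] <- 2 * stats::pnorm(-abs(eff / se))
      if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
        out$flag[i] <- "separation"
    }
  }
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out$p_bonferroni <- pmin(out$p * sum(!const), 1)
  out$p_bh <- NA_real_
  out$p_bh[!const] <- stats::p.adjust(out$p[!const], "BH")
  structure(list(results = out, mode = mode, n = n,
                 n_parameters = p_model, case_level = case_level,
                 covariates = if (is.null(covariates)) character(0) else colnames(covariates)),
            class = "ewas")
}

#' @export
print.ewas <- function(x, ...) {
  ok <- x$results$flag != "constant"
  cat(sprintf("EWAS (%s mode): %d CpGs, %d samples, case level '%s'\n",
              x$mode, nrow(x$results), x$n, x$case_level))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  cat(sprintf("  %d constant CpG(s) flagged; min p = %.3g\n",
              sum(!ok), suppressWarnings(min(x$results$p[ok], na.rm = TRUE))))
  invisible(x)
}

#' @export
summary.ewas <- function(object, p_threshold = 1e-5, ...) {
  r <- object$results[object$results$flag != "constant", ]
  structure(list(n_cpgs = nrow(object$results), n_tested = nrow(r),
                 n_samples = object$n, mode = object$mode,
                 lambda = genomic_lambda(r$p),
                 n_hits = sum(r$p < p_threshold, na.rm = TRUE),
                 p_threshold = p_threshold),
            class = "summary.ewas")
}

#' @export
print.summary.ewas <- function(x, ...) {
  cat(sprintf("EWAS summary: %d/%d CpGs tested on %d samples (%s mode)\n",
              x$n_tested, x$n_cpgs, x$n_samples, x$mode))
  cat(sprintf("  genomic inflation lambda = %.4f\n", x$lambda))
  cat(sprintf("  %d CpG(s) with p < %g\n", x$n_hits, x$p_threshold))
  invisible(x)
}

#' @export
coef.ewas <- function(object, ...) {
  stats::setNames(object$results$effect, object$results$cpg)
}

#' QQ and Manhattan plots for an EWAS fit
#'
#' @param x an `ewas` object.
#' @param type `"qq"` or `"manhattan"` (the latter requires `annotation`).
#' @param annotation annotation table as from [simulate_annotation()].
#' @param p_threshold significance line / label threshold.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ewas <- function(x, type = c("qq", "manhattan"), annotation = NULL,
                      p_threshold = 1e-5, ...) {
  type <- match.arg(type)
  r <- x$results[x$results$flag != "constant", ]
  if (type == "qq") {
    d <- qq_data(r$p)
    graphics::plot(d$expected, d$observed, xlab = "expected -log10(p)",
                   ylab = "observed -log10(p)",
                   main = sprintf("lambda = %.4f", genomic_lambda(r$p)), ...)
    graphics::abline(0, 1, col = "red")
  } else {
    if (is.null(annotation)) stop("manhattan plot needs an annotation table")
    d <- manhattan_data(x, annotation, p_threshold = p_threshold)
    graphics::plot(d$cum_pos, d$neg_log10_p, col = 1 + d$chr %% 2, pch = 20,
                   xlab = "genomic position", ylab = "-log10(p)", ...)
    graphics::abline(h = -log10(p_threshold), col = "red")
  }
  invisible(x)
}

#' Genomic inflation factor lambda
#'
#' Median of the one-degree-of-freedom chi-square quantiles of the observed
#' p-values divided by the null median (`qchisq(0.5, 1)` = 0.4549364).
#' Values near 1 indicate well-calibrated tests.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return lambda (scalar).
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Expected vs observed quantiles for a QQ plot
#'
#' @param p p-values in (0, 1\].
#' @return data.frame with `expected` and `observed` `-log10` p columns,
#'   observed sorted ascending in p; `expected_i = (i - 0.5)/n`.
#' @export
qq_data <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = -log10(sort(p)))
}

#' Report CpGs below a p-value threshold with their annotation
#'
#' Joins the EWAS results to the annotation table and returns the rows with
#' `p < p_threshold` ordered by ascending p — the shape of a top-hits
#' table (gene, chromosome, position, island relation, effect, SE, t, p).
#' CpGs with no gene annotation are rendered as `"-"`.
#'
#' @param fit an `ewas` object.
#' @param annotation annotation data.frame (`cpg`, `chr`, `pos`, `gene`,
#'   `feature`, `island_relation`).
#' @param p_threshold reporting threshold in (0, 1).
#' @return data.frame of annotated hits.
#' @export
annotate_hits <- function(fit, annotation, p_threshold = 1e-5) {
  stopifnot(inherits(fit, "ewas"))
  if (p_threshold <= 0 || p_threshold >= 1) stop("'p_threshold' must be in (0,1)")
  r <- fit$results[!is.na(fit$results$p) & fit$results$p < p_threshold, ]
  out <- merge(r, annotation, by = "cpg", all.x = TRUE, sort = FALSE)
  out$gene[is.na(out$gene) | out$gene == ""] <- "-"
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out[, c("cpg", "gene", "chr", "pos", "island_relation",
          "effect", "se", "t", "p", "df")]
}

#' Plot-ready Manhattan coordinates
#'
#' Maps every tested CpG to a cumulative genomic coordinate (chromosome
#' blocks ordered 1..22, each offset by the running maximum of the previous
#' chromosomes) with `-log10(p)` and a gene label where `p < p_threshold`.
#'
#' @param fit an `ewas` object; every tested CpG must be annotated.
#' @param annotation annotation data.frame.
#' @param p_threshold labelling threshold.
#' @return data.frame with `cpg`, `chr`, `pos`, `cum_pos`, `neg_log10_p`,
#'   `label`.
#' @export
manhattan_data <- function(fit, annotation, p_threshold = 1e-5) {
  stopifnot(inherits(fit, "ewas"))
  r <- fit$results[fit$results$flag != "constant", ]
  miss <- setdiff(r$cpg, annotation$cpg)
  if (length(miss))
    stop("unannotated CpG(s): ", paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" ... (%d total)", length(miss)) else "")
  d <- merge(r, annotation, by = "cpg", sort = FALSE)
  d <- d[order(d$chr, d$pos), ]
  offsets <- c(0, cumsum(as.numeric(
    tapply(d$pos, factor(d$chr, levels = sort(unique(d$chr))), max))))
  d$cum_pos <- d$pos + offsets[match(d$chr, sort(unique(d$chr)))]
  d$neg_log10_p <- -log10(d$p)
  d$label <- ifelse(d$p < p_threshold, d$gene, "")
  rownames(d) <- NULL
  d[, c("cpg", "chr", "pos", "cum_pos", "neg_log10_p", "label")]
}
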