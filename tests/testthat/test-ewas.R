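test_that("a CpG with identical group distributions gets effect 0 and p 1", {
  vals <- c(0.3, 0.4, 0.5, 0.6, 0.3, 0.4, 0.5, 0.6)
  b <- matrix(rep(vals, each = 3), 3, 8,
              dimnames = list(paste0("cg", 1:3), paste0("S", 1:8)))
  b[2, ] <- seq(0.1, 0.8, 0.1)  # non-null row for contrast
  fit <- ewas(b, rep(c("control", "case"), each = 4))
  expect_equal(fit$results$effect[1], 0, tolerance = 1e-12)
  expect_equal(fit$results$p[1], 1, tolerance = 1e-9)
})

test_that("the reported t equals effect/se for every CpG", {
  fit <- ewas_with_sv(planted_cohort(), k = 2)
  ok <- fit$results$flag == ""
  expect_equal(fit$results$t[ok], fit$results$effect[ok] / fit$results$se[ok],
               tolerance = 1e-9)
  expect_true(all(fit$results$df == fit$n - fit$n_parameters))
})

test_that("degrees of freedom equal samples minus fitted coefficients", {
  co <- simulate_cohort(sim_config(n_cases = 10, n_controls = 10, n_cpgs = 50, clock_cpg_count = 0,
                                   n_causal = 0, seed = 3))
  fit <- ewas(co$beta, co$samples$group,
              covariates = cbind(age = co$samples$age))
  expect_true(all(fit$results$df == 20 - 3))
})

test_that("planted effects are recovered within 20% at n = 200", {
  co <- planted_cohort()
  fit <- ewas_with_sv(co, k = 2)
  eff <- with(fit$results, setNames(effect, cpg))[co$truth$causal_cpgs]
  recovered <- mean(eff * sign(co$truth$effects))
  expect_gte(recovered, 0.12)
  expect_lte(recovered, 0.18)
  # estimated signs agree with the planted direction
  expect_true(all(sign(eff) == sign(co$truth$effects)))
})

test_that("constant CpG rows are flagged instead of crashing the scan", {
  co <- simulate_cohort(sim_config(n_cpgs = 30, n_causal = 0, clock_cpg_count = 0, seed = 2))
  b <- co$beta
  b[3, ] <- 0.5
  fit <- ewas(b, co$samples$group)
  expect_equal(fit$results$flag[3], "constant")
  expect_true(is.na(fit$results$p[3]))
  expect_true(all(!is.na(fit$results$p[-3])))
})

test_that("collinear covariates are rejected before fitting", {
  co <- simulate_cohort(sim_config(n_cpgs = 20, n_causal = 0, clock_cpg_count = 0, seed = 2))
  x <- co$samples$age
  expect_error(suppressWarnings(
    ewas(co$beta, co$samples$group, covariates = cbind(a = x, b = 2 * x))),
    "collinear")
})

test_that("logistic mode agrees with the planted direction", {
  co <- planted_cohort()
  fit <- ewas(co$beta[co$truth$causal_cpgs, ], co$samples$group,
              covariates = cbind(age = co$samples$age), mode = "logistic")
  agree <- sign(fit$results$effect) == sign(co$truth$effects[fit$results$cpg])
  expect_true(all(agree))
})

test_that("genomic inflation lambda behaves as a median chi-square ratio", {
  expect_equal(genomic_lambda(rep(0.5, 11)), 1)
  set.seed(42)
  expect_gt(genomic_lambda(runif(10000)), 0.95)
  expect_lt(genomic_lambda(runif(10000)), 1.05)
  # chi-square statistics scaled by 2 give lambda ~ 2
  set.seed(43)
  p2 <- pchisq(2 * rchisq(20000, 1), 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2), 2, tolerance = 0.06)
  expect_error(genomic_lambda(numeric(0)), "no p-values")
  expect_error(genomic_lambda(c(0.5, 0)), "0, 1")
})

test_that("the null EWAS is calibrated: type-I error and lambda", {
  fit <- ewas_with_sv(null_cohort())
  p <- fit$results$p
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
  expect_gte(genomic_lambda(p), 0.9)
  expect_lte(genomic_lambda(p), 1.1)
})

test_that("qq coordinates pair sorted observed with uniform expected quantiles", {
  d <- qq_data(0.5)
  expect_equal(d$expected, -log10(0.5))
  expect_equal(d$observed, -log10(0.5))
  d2 <- qq_data(c(0.2, 0.2, 0.2))
  expect_equal(nrow(d2), 3)
  set.seed(44)
  d3 <- qq_data(runif(10000))
  expect_lt(max(abs(d3$observed - d3$expected)), 0.5)
  expect_error(qq_data(c(0.1, 1.5)), "0, 1")
})

test_that("hit annotation joins, orders and blanks missing genes", {
  p <- c(1e-7, 1e-6, 0.5, 2e-6, 0.2, 1e-8, 3e-6, 4e-6, 5e-6, 6e-6, 0.9)
  fit <- fake_ewas(p)
  ann <- simulate_annotation(fit$results$cpg, seed = 3)
  ann$gene[ann$cpg == fit$results$cpg[1]] <- ""
  hits <- annotate_hits(fit, ann, 1e-5)
  expect_equal(nrow(hits), 8)
  expect_true(!is.unsorted(hits$p))
  expect_true("-" %in% hits$gene[hits$cpg == fit$results$cpg[1]])
  expect_equal(nrow(annotate_hits(fit, ann, 0.99)), sum(p < 0.99))
  expect_equal(nrow(annotate_hits(fit, ann, 1e-9)), 0)
})

test_that("manhattan coordinates accumulate across ordered chromosomes", {
  fit <- fake_ewas(c(1e-7, 0.2, 0.5, 0.8))
  ann <- data.frame(cpg = fit$results$cpg, chr = c(1, 1, 2, 2),
                    pos = c(100, 200, 50, 80),
                    gene = c("A", "B", "C", ""), feature = "Body",
                    island_relation = "Island", stringsAsFactors = FALSE)
  d <- manhattan_data(fit, ann)
  expect_equal(d$cum_pos, c(100, 200, 250, 280))
  expect_true(all(diff(d$cum_pos[d$chr == 1]) > 0))
  expect_equal(d$label, c("A", "", "", ""))  # only p < 1e-5 labelled
  # single chromosome: cumulative equals raw position
  ann1 <- ann; ann1$chr <- 1; ann1$pos <- c(10, 20, 30, 40)
  expect_equal(manhattan_data(fit, ann1)$cum_pos, c(10, 20, 30, 40))
  expect_error(manhattan_data(fit, ann[-1, ]), "unannotated")
})
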