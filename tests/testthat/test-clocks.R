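test_that("clock application is the affine form with optional transform", {
  b <- matrix(runif(20, 0.2, 0.8), 4, 5,
              dimnames = list(paste0("cg", 1:4), paste0("S", 1:5)))
  ck <- clock_model("const", intercept = 7,
                    weights = setNames(rep(0, 4), paste0("cg", 1:4)))
  expect_true(all(apply_clock(b, ck) == 7))
  # horvath transform at raw 0 gives the anchor age
  ck0 <- clock_model("h", intercept = 0, weights = numeric(0),
                     transform = "horvath", adult_age = 20)
  expect_true(all(apply_clock(b, ck0) == 20))
  # linearity: doubling the weights doubles raw minus intercept
  w <- setNames(runif(4, -1, 1), paste0("cg", 1:4))
  a1 <- apply_clock(b, clock_model("c1", 2, w))
  a2 <- apply_clock(b, clock_model("c2", 2, 2 * w))
  expect_equal(a2 - 2, 2 * (a1 - 2), tolerance = 1e-12)
})

test_that("missing clock CpGs follow the declared policy", {
  b <- matrix(runif(10, 0.2, 0.8), 2, 5,
              dimnames = list(c("cg1", "cg2"), paste0("S", 1:5)))
  ck <- clock_model("c", 0, setNames(c(1, 1, 1), c("cg1", "cg2", "cgMISS")))
  expect_error(apply_clock(b, ck), "cgMISS")
  imputed <- apply_clock(b, ck, missing_policy = "mean_impute")
  expect_equal(unname(imputed), unname(colSums(b) + colMeans(b)))
})

test_that("the Horvath transform pair is exact and mutually inverse", {
  expect_equal(horvath_inverse(0, 20), 20)
  expect_equal(horvath_inverse(-log(21), 20), 0)
  for (x in c(-2, -0.5, 0, 1.3))
    expect_equal(horvath_forward(horvath_inverse(x, 20), 20), x, tolerance = 1e-12)
  # continuity and monotonicity across the join
  xs <- seq(-3, 3, 0.01)
  ys <- horvath_inverse(xs, 20)
  expect_true(all(diff(ys) > 0))
})

test_that("a jointly simulated clock recovers true ages", {
  cfg <- sim_config(n_cases = 12, n_controls = 11, n_cpgs = 2000,
                    n_causal = 0, clock_cpg_count = 50, seed = 7)
  co <- simulate_cohort(cfg)
  for (tr in c("identity", "horvath")) {
    ck <- simulate_clock(50, tr, seed = 7, age_range = cfg$age_range)
    ages <- apply_clock(co$beta, ck)
    expect_gt(cor(ages, co$truth$ages), 0.9)
  }
})

test_that("age acceleration is the regression residual", {
  age <- c(10, 12, 14, 16, 18)
  expect_equal(unname(age_acceleration(age, age)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(age_acceleration(age + 5, age)), rep(0, 5), tolerance = 1e-12)
  # invariant to adding a constant
  e <- age + rnorm(5)
  expect_equal(age_acceleration(e + 3, age), age_acceleration(e, age),
               tolerance = 1e-12)
  # a planted fast ager has the largest residual
  set.seed(1)
  chron <- runif(50, 10, 18)
  epi <- chron + rnorm(50, 0, 0.5)
  epi[17] <- chron[17] + 10
  expect_equal(unname(which.max(age_acceleration(epi, chron))), 17L)
  expect_error(age_acceleration(epi, rep(12, 50)), "constant")
})

test_that("trait correlations switch method on the normality screen", {
  set.seed(2)
  n <- 100
  ages <- data.frame(clockA = rnorm(n, 14, 2))
  sheet <- data.frame(lin = 2 * ages$clockA + 1,
                      noise = rnorm(n),
                      bin = rbinom(n, 1, 0.5),
                      const = rep(3, n))
  out <- clock_trait_cor(ages, sheet, c("lin", "noise", "bin", "const"))
  lin <- out[out$trait == "lin", ]
  expect_equal(lin$r, 1, tolerance = 1e-9)
  expect_lt(lin$p, 1e-12)
  expect_lt(abs(out$r[out$trait == "noise"]), 0.25)
  expect_equal(out$method[out$trait == "bin"], "spearman")
  expect_equal(out$flag[out$trait == "const"], "constant")
  # symmetric under swapping the variables
  swapped <- clock_trait_cor(data.frame(clockA = sheet$noise),
                             data.frame(x = ages$clockA), "x")
  expect_equal(swapped$r, out$r[out$trait == "noise"], tolerance = 1e-12)
})

test_that("stepwise selection keeps a strong predictor and drops pure noise", {
  n <- 100
  keep_strong <- logical(100)
  set.seed(5)
  for (r in 1:100) {
    sheet <- data.frame(strong = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                        n3 = rnorm(n), n4 = rnorm(n))
    y <- 3 * sheet$strong + rnorm(n)  # R^2 ~ 0.9
    keep_strong[r] <- "strong" %in%
      stepwise_clock_regression(y, sheet, names(sheet))$selected
  }
  expect_gte(mean(keep_strong), 0.95)

  set.seed(6)
  none <- replicate(200, {
    sheet <- data.frame(n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
    y <- rnorm(n)
    length(stepwise_clock_regression(y, sheet, names(sheet))$selected) == 0
  })
  expect_gt(mean(none), 0.5)
})

test_that("stepwise confidence intervals follow the t quantile identity", {
  set.seed(7)
  sheet <- data.frame(x = rnorm(50), z = rnorm(50))
  y <- 2 * sheet$x + rnorm(50)
  out <- stepwise_clock_regression(y, sheet, c("x", "z"))
  df <- out$model$df.residual
  expect_equal(out$terms$ci_lo,
               out$terms$estimate - qt(0.975, df) * out$terms$se, tolerance = 1e-12)
  expect_equal(as.matrix(out$terms[c("ci_lo", "ci_hi")]),
               unname(confint(out$model))[, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(stepwise_clock_regression(y, sheet, character(0)), "empty")
  sheet$dup <- sheet$x
  expect_error(stepwise_clock_regression(y, sheet, c("x", "dup")), "collinearity")
})
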