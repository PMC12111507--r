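test_that("threshold stratification selects by strict inequality and nests", {
  fit <- fake_ewas(c(1e-7, 5e-6, 2e-3))
  sets <- suppressMessages(stratify_cpgs(fit, c(1e-6, 1e-5, 1e-2)))
  expect_equal(unname(vapply(sets, length, 1L)), c(1, 2, 3))
  # default ladder is the six decades
  defaults <- suppressMessages(stratify_cpgs(fit))
  expect_length(defaults, 6)
  expect_equal(names(defaults),
               c("1e-06", "1e-05", "1e-04", "1e-03", "1e-02", "1e-01"))
  # nesting
  for (i in seq_len(length(defaults) - 1))
    expect_true(all(defaults[[i]] %in% defaults[[i + 1]]))
  # threshold below the minimum p: empty set allowed and flagged
  expect_message(s0 <- stratify_cpgs(fit, c(1e-9, 1e-2)), "empty")
  expect_length(s0[[1]], 0)
  expect_error(stratify_cpgs(fit, c(1e-2, 1e-6)), "increasing")
})

test_that("the raw score is the sum of M times Z over the selected CpGs", {
  fit <- fake_ewas(c(1e-7, 0.5), effect = c(0.3, 0), se = c(0.1, 1))  # Z = 3, 0
  m <- matrix(c(2, 5, 1, 7), 2, 2,
              dimnames = list(c("cg00001", "cg00002"), c("S1", "S2")))
  expect_equal(unname(compute_mrs(m, fit, "cg00001")), c(2 * 3, 1 * 3))
  # a CpG with Z = 0 contributes nothing
  expect_equal(compute_mrs(m, fit, c("cg00001", "cg00002")),
               compute_mrs(m, fit, "cg00001"))
  # all-zero Z gives zero scores
  fit0 <- fake_ewas(c(0.5, 0.5), effect = c(0, 0), se = c(1, 1))
  expect_equal(unname(compute_mrs(m, fit0, c("cg00001", "cg00002"))), c(0, 0))
  expect_error(compute_mrs(m, fit, "cgZZ"), "missing from the matrix")
})

test_that("z-scoring is exact and affine invariant", {
  expect_equal(unname(zscore_mrs(c(1, 2, 3))), c(-1, 0, 1))
  x <- c(4.2, -1, 7, 0.3, 2)
  expect_equal(zscore_mrs(10 * x + 3), zscore_mrs(x), tolerance = 1e-12)
  expect_error(zscore_mrs(rep(2, 5), label = "1e-02"), "1e-02")
  z <- zscore_mrs(rnorm(20))
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
})

test_that("profiles are z-normalized per threshold and permutation equivariant", {
  co <- simulate_cohort(sim_config(n_cases = 12, n_controls = 11, n_cpgs = 2000,
                                   n_causal = 20, seed = 7))
  m <- beta_to_m(co$beta)
  fit <- ewas_with_sv(co)
  prof <- suppressMessages(mrs_profile(m, fit))
  for (th in names(prof$n_cpgs)) {
    z <- prof$scores$z[prof$scores$threshold == th]
    if (all(is.na(z))) next
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
  expect_true(!is.unsorted(unname(prof$n_cpgs)))
  # permuting samples permutes scores identically
  perm <- sample(ncol(m))
  prof_p <- suppressMessages(mrs_profile(m[, perm], fit))
  th1 <- names(prof$n_cpgs)[prof$n_cpgs > 0][1]
  a <- prof$scores[prof$scores$threshold == th1, ]
  b <- prof_p$scores[prof_p$scores$threshold == th1, ]
  expect_equal(b$raw[match(a$sample_id, b$sample_id)], a$raw)
})

test_that("planted-effect cohorts separate cases from controls at every informative threshold", {
  co <- simulate_cohort(sim_config(n_cases = 12, n_controls = 11, n_cpgs = 2000,
                                   n_causal = 20, seed = 7))
  m <- beta_to_m(co$beta)
  fit <- ewas_with_sv(co)
  prof <- suppressMessages(mrs_profile(m, fit))
  cs <- co$samples$group == "case"
  for (th in names(prof$n_cpgs)[prof$n_cpgs > 0]) {
    z <- prof$scores$z[prof$scores$threshold == th]
    expect_gt(mean(z[cs]), mean(z[!cs]))
  }
})

test_that("score-phenotype association is calibrated, recovers a planted slope, and flags separation", {
  co <- planted_cohort()
  m <- beta_to_m(co$beta)
  fit <- ewas_with_sv(co, k = 2)
  prof <- suppressMessages(mrs_profile(m, fit))
  sheet <- co$samples
  z <- prof$scores$z[prof$scores$threshold == "1e-02"]

  # independent phenotype: null association in >= 90% of replicates
  set.seed(42)
  null_p <- replicate(100, {
    sheet$noise <- rnorm(nrow(sheet))
    associate_mrs(prof, sheet, "noise", family = "linear")$p[5]
  })
  expect_gte(mean(null_p > 0.05), 0.9)

  # planted logistic dependence, slope 1
  set.seed(43)
  sheet$flagged <- rbinom(nrow(sheet), 1, plogis(z))
  est <- associate_mrs(prof, sheet, "flagged", family = "logistic")
  b <- est$beta[est$threshold == "1e-02"]
  expect_gte(b, 0.6)
  expect_lte(b, 1.4)

  # deterministic threshold of the score: separation flagged, not silent
  sheet$det <- as.integer(z > 0)
  sep <- associate_mrs(prof, sheet, "det", family = "logistic")
  expect_true(any(grepl("separation", sep$flag)))

  # one-class binary phenotype is an error
  sheet$allsame <- 1L
  expect_error(associate_mrs(prof, sheet, "allsame", family = "logistic"),
               "single class")
})
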