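# Hand-built EWAS result with prescribed statistics, for testing the
# operations downstream of the association scan in isolation.
fake_ewas <- function(p, effect = rep(0.1, length(p)),
                      se = rep(0.05, length(p)),
                      cpg = sprintf("cg%05d", seq_along(p))) {
  structure(list(results = data.frame(cpg = cpg, effect = effect, se = se,
                                      t = effect / se, p = p, df = 20L,
                                      flag = "", stringsAsFactors = FALSE),
                 mode = "meth_outcome", n = 23L, n_parameters = 3L,
                 case_level = "case", covariates = character(0)),
            class = "ewas")
}

# Default-covariate EWAS on a simulated cohort (age + sex + k surrogate
# variables), mirroring the pipeline's standard model.
ewas_with_sv <- function(cohort, k = 5L, on = c("beta", "m")) {
  on <- match.arg(on)
  m <- beta_to_m(cohort$beta)
  covars <- cbind(age = cohort$samples$age, sex = as.numeric(cohort$samples$sex))
  if (k > 0L) covars <- cbind(covars, estimate_sv(m, cohort$samples$group, k = k))
  ewas(if (on == "m") m else cohort$beta, cohort$samples$group, covariates = covars)
}

# Cohorts reused across test files; built lazily and cached per session.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, cfg) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- simulate_cohort(cfg)
  .cohort_cache[[key]]
}
null_cohort <- function()
  cached_cohort("null", sim_config(n_cases = 50, n_controls = 50, n_cpgs = 5000,
                                   n_causal = 0, seed = 42))
planted_cohort <- function()
  cached_cohort("planted", sim_config(n_cases = 100, n_controls = 100,
                                      n_cpgs = 1000, n_causal = 50,
                                      effect_delta = 0.15, seed = 42))
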