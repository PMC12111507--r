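#' Configuration for a synthetic methylation cohort
#'
#' Collects the dimensions and effect sizes of a simulated case-control
#' DNA-methylation cohort. Defaults mirror a small clinical study of
#' early-onset psychosis: 12 cases vs 11 controls, 10,000 CpGs, ages
#' 10-18 years, and beta-scale residual dispersion typical of
#' inter-individual array variation.
#'
#' @param n_cases,n_controls sample counts per group.
#' @param n_cpgs total number of CpG sites (includes the clock CpGs).
#' @param n_causal number of CpGs with a planted case-control difference.
#' @param effect_delta beta-scale mean group difference at each causal CpG
#'   (cases minus controls, random sign per CpG).
#' @param n_latent number of latent batch components.
#' @param latent_sd standard deviation of the per-CpG latent loadings
#'   (logit scale).
#' @param age_range numeric length-2, min and max age in years.
#' @param clock_cpg_count number of CpGs carrying an age signal; these are
#'   the sites a jointly simulated clock ([simulate_clock()]) reads.
#' @param noise_sd beta-scale residual standard deviation per CpG.
#' @param seed integer seed; all randomness in the generators flows from it.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [simulate_clock()], [simulate_annotation()]
#' @export
sim_config <- function(n_cases = 12L, n_controls = 11L, n_cpgs = 10000L,
                       n_causal = 20L, effect_delta = 0.15, n_latent = 2L,
                       latent_sd = 0.2, age_range = c(10, 18),
                       clock_cpg_count = 50L, noise_sd = 0.05, seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_cpgs = as.integer(n_cpgs), n_causal = as.integer(n_causal),
              effect_delta = effect_delta, n_latent = as.integer(n_latent),
              latent_sd = latent_sd, age_range = as.numeric(age_range),
              clock_cpg_count = as.integer(clock_cpg_count),
              noise_sd = noise_sd, seed = as.integer(seed))
  counts <- c("n_cases", "n_controls", "n_cpgs")
  for (nm in counts)
    if (cfg[[nm]] <= 0L) stop("'", nm, "' must be a positive count")
  if (cfg$n_causal < 0L) stop("'n_causal' must be >= 0")
  if (cfg$n_latent < 0L || cfg$clock_cpg_count < 0L)
    stop("'n_latent' and 'clock_cpg_count' must be >= 0")
  if (cfg$n_causal + cfg$clock_cpg_count > cfg$n_cpgs)
    stop("n_causal + clock_cpg_count exceeds n_cpgs")
  if (abs(cfg$effect_delta) >= 0.5)
    stop("'effect_delta' of ", cfg$effect_delta,
         " cannot keep beta in (0,1) around mid-range baselines")
  if (cfg$noise_sd <= 0 || cfg$latent_sd < 0) stop("dispersions must be positive")
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0)
    stop("'age_range' must be (min, max) with min < max")
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic methylation cohort configuration\n")
  cat(sprintf("  samples: %d cases / %d controls\n", x$n_cases, x$n_controls))
  cat(sprintf("  CpGs: %d (%d causal, delta = %g; %d clock)\n",
              x$n_cpgs, x$n_causal, x$effect_delta, x$clock_cpg_count))
  cat(sprintf("  latent components: %d (loading sd %g); noise sd %g (beta scale)\n",
              x$n_latent, x$latent_sd, x$noise_sd))
  cat(sprintf("  ages: U(%g, %g); seed %d\n", x$age_range[1], x$age_range[2], x$seed))
  invisible(x)
}

# Age-signal structure shared by simulate_cohort() and simulate_clock().
# Drawn from its own RNG stream (a fixed offset of the user seed) so the two
# generators agree without entangling the rest of the cohort randomness.
clock_signal <- function(count, seed) {
  if (count == 0L)
    return(list(ids = character(0), base = numeric(0), slope = numeric(0)))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(bitwXor(as.integer(seed), 10007L))
  list(ids = sprintf("cgclk%05d", seq_len(count)),
       base = stats::runif(count, 0.3, 0.7),
       slope = sample(c(-1, 1), count, replace = TRUE) * stats::runif(count, 0.5, 1.0))
}

# beta-scale residual sd -> logit-scale sd via the delta method,
# with the derivative floored so boundary CpGs do not explode.
logit_sd <- function(beta_sd, p) beta_sd / pmax(p * (1 - p), 0.1)

#' Simulate a case-control methylation cohort with known ground truth
#'
#' Beta values are built on the logit scale (a Gaussian linear model pushed
#' through the logistic function), which guarantees every value lies in
#' (0,1) without clipping and keeps the M-value transform exact. Cases and
#' controls differ in expectation by `effect_delta` at the causal CpGs only;
#' the last `clock_cpg_count` CpGs carry a linear age signal; latent batch
#' components and per-CpG noise are added for all sites. Auxiliary
#' phenotypes (GAF, admissions, comorbidities, symptom flags) are monotone
#' functions of group plus noise, so score-phenotype associations exist by
#' construction.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `meth_cohort`: a list with
#'   \describe{
#'     \item{beta}{CpG x sample matrix of methylation fractions in (0,1).}
#'     \item{samples}{data.frame of per-sample phenotypes (`group`, `age`,
#'       `sex` coded 0 = male / 1 = female, `schooling`, `gaf`,
#'       `admissions`, `admitted`, `comorbidities`, and binary symptom
#'       flags).}
#'     \item{truth}{ground truth: causal CpG ids with signed beta-scale
#'       effects, latent loadings, clock CpG ids, true ages.}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ck <- clock_signal(config$clock_cpg_count, config$seed)
  set.seed(config$seed)

  n <- config$n_cases + config$n_controls
  n_plain <- config$n_cpgs - config$clock_cpg_count
  cpg_ids <- c(sprintf("cg%08d", seq_len(n_plain)), ck$ids)
  sample_ids <- sprintf("S%03d", seq_len(n))
  is_case <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1L, 0.5)
  age_centre <- mean(config$age_range)
  age_scale <- diff(config$age_range) / 2
  z_age <- (age - age_centre) / age_scale

  # baselines: bimodal-ish mixture like real arrays, causal sites mid-range
  comp <- sample.int(3L, n_plain, replace = TRUE, prob = c(0.35, 0.3, 0.35))
  base <- c(stats::rbeta(n_plain, 2, 10), stats::rbeta(n_plain, 5, 5),
            stats::rbeta(n_plain, 10, 2))[(comp - 1L) * n_plain + seq_len(n_plain)]
  causal <- if (config$n_causal > 0L) sort(sample.int(n_plain, config$n_causal)) else integer(0)
  base[causal] <- stats::runif(config$n_causal, 0.25, 0.75)
  sign_c <- sample(c(-1, 1), config$n_causal, replace = TRUE)

  # per-CpG, per-group target beta means; group difference = signed delta
  base_all <- c(base, ck$base)
  mu_ctrl <- base_all
  mu_case <- base_all
  mu_ctrl[causal] <- base[causal] - sign_c * config$effect_delta / 2
  mu_case[causal] <- base[causal] + sign_c * config$effect_delta / 2

  logit_mu <- outer(stats::qlogis(mu_ctrl), rep(1, n))
  if (config$n_causal > 0L) {
    d <- stats::qlogis(mu_case[causal]) - stats::qlogis(mu_ctrl[causal])
    logit_mu[causal, ] <- logit_mu[causal, ] + d %o% as.numeric(is_case)
  }

  # age signal on the clock CpGs (logit-linear in scaled age)
  if (config$clock_cpg_count > 0L) {
    idx <- n_plain + seq_len(config$clock_cpg_count)
    logit_mu[idx, ] <- logit_mu[idx, ] + ck$slope %o% z_age
  }

  # small sex effect on a random 2% of non-causal, non-clock CpGs
  sex_pool <- setdiff(seq_len(n_plain), causal)
  sex_idx <- sample(sex_pool, max(0L, round(0.02 * length(sex_pool))))
  if (length(sex_idx))
    logit_mu[sex_idx, ] <- logit_mu[sex_idx, ] +
      (sample(c(-0.5, 0.5), length(sex_idx), TRUE)) %o% as.numeric(sex)

  # latent batch components
  loadings <- matrix(0, config$n_cpgs, config$n_latent)
  if (config$n_latent > 0L) {
    loadings <- matrix(stats::rnorm(config$n_cpgs * config$n_latent, 0, config$latent_sd),
                       config$n_cpgs, config$n_latent)
    scores <- matrix(stats::rnorm(n * config$n_latent), config$n_latent, n, byrow = TRUE)
    logit_mu <- logit_mu + loadings %*% scores
  }

  noise <- matrix(stats::rnorm(config$n_cpgs * n), config$n_cpgs, n) *
    logit_sd(config$noise_sd, base_all)
  beta <- stats::plogis(logit_mu + noise)
  dimnames(beta) <- list(cpg_ids, sample_ids)

  samples <- data.frame(
    sample_id = sample_ids,
    group = factor(ifelse(is_case == 1L, "case", "control"),
                   levels = c("control", "case")),
    age = age,
    sex = sex,
    schooling = pmax(0, round(age - 6 + stats::rnorm(n, 0, 1.2))),
    gaf = pmin(100, pmax(1, round(75 - 30 * is_case + stats::rnorm(n, 0, 8)))),
    admissions = stats::rpois(n, 0.2 + 1.3 * is_case),
    comorbidities = 1L + stats::rpois(n, 0.8 + 0.7 * is_case),
    panic_disorder = stats::rbinom(n, 1L, stats::plogis(-2 + 2.2 * is_case)),
    auditory_hallucinations = stats::rbinom(n, 1L, stats::plogis(-2 + 2.2 * is_case)),
    visual_hallucinations = stats::rbinom(n, 1L, stats::plogis(-2 + 2.2 * is_case)),
    stringsAsFactors = FALSE)
  samples$admitted <- as.integer(samples$admissions > 0)

  effects <- numeric(0)
  if (config$n_causal > 0L) {
    effects <- sign_c * config$effect_delta
    names(effects) <- cpg_ids[causal]
  }
  rownames(loadings) <- cpg_ids
  truth <- structure(list(causal_cpgs = cpg_ids[causal], effects = effects,
                          latent_loadings = loadings, clock_cpgs = ck$ids,
                          ages = stats::setNames(age, sample_ids)),
                     class = "ground_truth")
  structure(list(beta = beta, samples = samples, truth = truth, config = config),
            class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic methylation cohort: %d CpGs x %d samples (%d cases, %d controls)\n",
              nrow(x$beta), ncol(x$beta), sum(x$samples$group == "case"),
              sum(x$samples$group == "control")))
  cat(sprintf("  %d causal CpGs (|delta| = %g), %d clock CpGs, seed %d\n",
              length(x$truth$causal_cpgs), x$config$effect_delta,
              length(x$truth$clock_cpgs), x$config$seed))
  invisible(x)
}

#' Simulate a linear clock matched to the cohort generator's age signal
#'
#' Builds a [clock_model()] whose weights invert the age signal planted by
#' [simulate_cohort()] at the clock CpGs: when both are called with the same
#' `seed` (and `n_cpgs` equal to the configuration's `clock_cpg_count`), the
#' clock applied to the simulated beta matrix recovers the true ages. For a
#' Horvath-style transform the clock predicts the forward-transformed age
#' (linearised at the centre of `age_range`) and [apply_clock()] back-maps.
#'
#' @param n_cpgs number of clock CpGs; 0 yields a constant intercept-only
#'   clock.
#' @param transform `"identity"` or `"horvath"`.
#' @param seed same seed as the cohort the clock should be applied to.
#' @param age_range,adult_age age window of the cohort and the Horvath
#'   anchor age (years).
#' @return A `clock_model`.
#' @export
simulate_clock <- function(n_cpgs, transform = c("identity", "horvath"),
                           seed = 1L, age_range = c(10, 18), adult_age = 20) {
  transform <- match.arg(transform)
  centre <- mean(age_range)
  scale <- diff(age_range) / 2
  if (n_cpgs == 0L)
    return(clock_model("sim-clock", intercept = if (transform == "identity")
      centre else horvath_forward(centre, adult_age),
      weights = numeric(0), transform = transform, adult_age = adult_age))
  ck <- clock_signal(n_cpgs, seed)
  # invert each CpG's logit-linear age signal, averaged across sites:
  # beta_i ~ base_i + base_i(1-base_i) * slope_i * (age-centre)/scale
  w <- scale / (n_cpgs * ck$base * (1 - ck$base) * ck$slope)
  intercept <- centre - sum(w * ck$base)
  if (transform == "horvath") {
    # clock raw output targets the forward-transformed age, linearised at
    # the cohort age centre: t(age) ~ t(centre) + t'(centre) (age - centre)
    dfwd <- if (centre < adult_age) 1 / (centre + 1) else 1 / (adult_age + 1)
    intercept <- horvath_forward(centre, adult_age) + dfwd * (intercept - centre)
    w <- w * dfwd
  }
  clock_model("sim-clock", intercept = intercept,
              weights = stats::setNames(w, ck$ids),
              transform = transform, adult_age = adult_age)
}

#' Simulate a CpG annotation table
#'
#' Produces one annotation row per CpG id with array-style columns:
#' chromosome (1-22), 1-based position, gene symbol (blank for intergenic
#' sites), feature class and CpG-island relation. Coordinates are
#' synthetic and carry no genomic meaning.
#'
#' @param cpg_ids unique character vector of CpG ids.
#' @param seed integer seed.
#' @return data.frame with columns `cpg`, `chr`, `pos`, `gene`, `feature`,
#'   `island_relation`.
#' @export
simulate_annotation <- function(cpg_ids, seed = 1L) {
  if (length(cpg_ids) == 0L) stop("'cpg_ids' must be nonempty")
  if (anyDuplicated(cpg_ids)) stop("duplicate CpG ids in 'cpg_ids'")
  set.seed(as.integer(seed))
  n <- length(cpg_ids)
  chr <- sample.int(22L, n, replace = TRUE)
  pos <- integer(n)
  # unique, sorted positions within each chromosome so cumulative
  # Manhattan coordinates are strictly increasing
  for (c in unique(chr)) {
    i <- which(chr == c)
    pos[i] <- sort(sample.int(2.4e8, length(i)))
  }
  feature <- sample(c("Body", "Exon", "TSS200", "intergenic"), n, replace = TRUE,
                    prob = c(0.4, 0.2, 0.15, 0.25))
  gene <- ifelse(feature == "intergenic", "",
                 sprintf("GENE%04d", sample.int(5000L, n, replace = TRUE)))
  data.frame(cpg = cpg_ids, chr = chr, pos = pos, gene = gene,
             feature = feature,
             island_relation = sample(c("Island", "N Shore", "S Shore", "Open Sea"),
                                      n, replace = TRUE, prob = c(0.25, 0.125, 0.125, 0.5)),
             stringsAsFactors = FALSE)
}
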