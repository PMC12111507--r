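#' Configuration for a full pipeline run
#'
#' Collects input paths and stage parameters for [run_pipeline()]. All
#' paths must exist when the run starts; `thresholds` must be ascending.
#'
#' @param beta path to the beta matrix (TSV/CSV, gzip ok).
#' @param samples path to the sample sheet CSV (needs `sample_id`,
#'   `group`, `age`, `sex`).
#' @param annotation optional annotation TSV path.
#' @param blacklist optional path, one CpG id per line.
#' @param clocks character vector of clock coefficient file paths.
#' @param out_dir output directory.
#' @param sd_threshold low-variability filter threshold (beta-scale SD).
#' @param sv_k number of surrogate variables (0 disables).
#' @param m_offset beta-to-M offset.
#' @param ewas_mode `"meth_outcome"` or `"logistic"`.
#' @param ewas_on `"beta"` or `"m"`: scale the association model sees.
#' @param p_threshold hit-reporting threshold.
#' @param mrs_thresholds ascending risk-score p-value cutoffs.
#' @param stats_variables named character vector for [table1_report()]
#'   (NULL disables the stage).
#' @param seed integer seed echoed into the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(beta, samples, annotation = NULL, blacklist = NULL,
                            clocks = character(0), out_dir,
                            sd_threshold = 0.01, sv_k = 5L, m_offset = 1e-6,
                            ewas_mode = "meth_outcome", ewas_on = "beta",
                            p_threshold = 1e-5, mrs_thresholds = 10^(-6:-1),
                            stats_variables = NULL, seed = 1L) {
  for (p in c(beta, samples, annotation, blacklist, clocks))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  if (is.unsorted(mrs_thresholds, strictly = TRUE))
    stop("'mrs_thresholds' must be ascending")
  structure(list(beta = beta, samples = samples, annotation = annotation,
                 blacklist = blacklist, clocks = clocks, out_dir = out_dir,
                 sd_threshold = sd_threshold, sv_k = as.integer(sv_k),
                 m_offset = m_offset, ewas_mode = ewas_mode, ewas_on = ewas_on,
                 p_threshold = p_threshold, mrs_thresholds = mrs_thresholds,
                 stats_variables = stats_variables, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  args <- list(beta = rel(y$beta), samples = rel(y$samples),
               annotation = rel(y$annotation), blacklist = rel(y$blacklist),
               clocks = if (is.null(y$clocks)) character(0) else unlist(lapply(y$clocks, rel)),
               out_dir = rel(y$out_dir))
  for (k in c("sd_threshold", "sv_k", "m_offset", "ewas_mode", "ewas_on",
              "p_threshold", "mrs_thresholds", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$stats_variables)) args$stats_variables <- unlist(y$stats_variables)
  do.call(pipeline_config, args)
}

#' Run the full methylation analysis pipeline
#'
#' Executes preprocess (low-variability filter, blacklist, M-values,
#' surrogate variables) -> EWAS -> hit annotation -> methylation risk
#' scores -> clocks -> group statistics, writing every stage output and a
#' JSON manifest of per-stage CpG/sample accounting to `out_dir`. Identical
#' config and seed produce byte-identical outputs. A stage failure aborts
#' the run but the manifest written so far is flushed to disk.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(config = config[setdiff(names(unclass(config)), "stats_variables")],
                   package_version = as.character(utils::packageVersion("epimrs")),
                   stages = list())
  flush_manifest <- function() {
    m <- manifest
    m$config <- lapply(unclass(config), function(x) x)
    jsonlite::write_json(m, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE, pretty = TRUE)
  }
  stage <- function(name, n_in, n_out, notes = "") {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, n_in = n_in, n_out = n_out, notes = notes)
  }
  on.exit(flush_manifest())

  beta <- read_beta_matrix(config$beta)
  sheet <- read_sample_sheet(config$samples)
  if (!all(colnames(beta) %in% sheet$sample_id))
    stop("matrix samples missing from sheet")
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  stage("read", nrow(beta), nrow(beta),
        sprintf("%d samples", ncol(beta)))

  flt <- filter_low_variability(beta, config$sd_threshold)
  stage("filter_low_variability", nrow(beta), nrow(flt$beta),
        sprintf("%d removed", length(flt$removed)))
  beta <- flt$beta
  if (!is.null(config$blacklist)) {
    bl <- readLines(config$blacklist)
    n_in <- nrow(beta)
    beta <- exclude_blacklist(beta, bl)
    stage("exclude_blacklist", n_in, nrow(beta),
          sprintf("%d ids listed", length(bl)))
  }
  m <- beta_to_m(beta, config$m_offset)
  write_beta_matrix(m, file.path(config$out_dir, "mvalues.tsv.gz"), id_col = "cpg")
  stage("beta_to_m", nrow(beta), nrow(m), sprintf("offset %g", config$m_offset))

  covars <- cbind(age = sheet$age, sex = as.numeric(sheet$sex))
  if (config$sv_k > 0L) {
    sv <- estimate_sv(m, sheet$group, k = config$sv_k)
    covars <- cbind(covars, sv)
    data.table::fwrite(data.frame(sample_id = rownames(sv), sv),
                       file.path(config$out_dir, "surrogate_variables.csv"))
    stage("estimate_sv", ncol(m), config$sv_k, "residual PCA on M-values")
  }

  fit <- ewas(if (config$ewas_on == "m") m else beta, sheet$group,
              covariates = covars, mode = config$ewas_mode)
  data.table::fwrite(fit$results, file.path(config$out_dir, "ewas.tsv"), sep = "\t")
  stage("ewas", nrow(m), nrow(fit$results),
        sprintf("lambda %.4f", genomic_lambda(
          fit$results$p[fit$results$flag != "constant"])))

  if (!is.null(config$annotation)) {
    ann <- data.table::fread(config$annotation, data.table = FALSE)
    hits <- annotate_hits(fit, ann, config$p_threshold)
    data.table::fwrite(hits, file.path(config$out_dir, "hits.tsv"), sep = "\t")
    md <- manhattan_data(fit, ann, config$p_threshold)
    data.table::fwrite(md, file.path(config$out_dir, "manhattan.tsv"), sep = "\t")
    stage("annotate_hits", nrow(fit$results), nrow(hits),
          sprintf("p < %g", config$p_threshold))
  }
  qd <- qq_data(fit$results$p[fit$results$flag != "constant"])
  data.table::fwrite(qd, file.path(config$out_dir, "qq.tsv"), sep = "\t")

  prof <- mrs_profile(m, fit, config$mrs_thresholds)
  data.table::fwrite(prof$scores, file.path(config$out_dir, "mrs_scores.csv"))
  stage("mrs", nrow(fit$results), length(config$mrs_thresholds),
        paste(prof$n_cpgs, collapse = "/"))

  if (length(config$clocks)) {
    ages <- lapply(config$clocks, function(p) {
      cm <- read_clock_model(p)
      apply_clock(beta, cm, missing_policy = "mean_impute", min_coverage = 0)
    })
    names(ages) <- vapply(config$clocks, function(p) read_clock_model(p)$name, "")
    ages_df <- data.frame(sample_id = colnames(beta), ages, check.names = FALSE)
    data.table::fwrite(ages_df, file.path(config$out_dir, "ages.csv"))
    stage("clocks", length(config$clocks), length(config$clocks),
          paste(names(ages), collapse = ","))
  }

  if (!is.null(config$stats_variables)) {
    tab1 <- table1_report(sheet, config$stats_variables)
    data.table::fwrite(tab1, file.path(config$out_dir, "table1.csv"))
    stage("stats", length(config$stats_variables), nrow(tab1), "")
  }
  flush_manifest()
  invisible(manifest)
}
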