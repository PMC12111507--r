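# fread with transparent gzip (via a decompressing connection, so no
# optional dependency is needed for .gz inputs)
fread_any <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), header = TRUE,
                      data.table = FALSE, fill = FALSE)
  } else {
    data.table::fread(path, header = TRUE, data.table = FALSE, fill = FALSE)
  }
}

#' Read a beta (or M-value) matrix from TSV/CSV
#'
#' First column = CpG id, header = sample ids; gzip files are handled
#' transparently. Duplicate ids and out-of-range beta values are errors
#' that name the offending CpG and sample.
#'
#' @param path file path (`.tsv`, `.csv`, optionally `.gz`).
#' @param check_range validate values lie in \[0,1\] (disable for M-value
#'   matrices).
#' @return CpG x sample numeric matrix.
#' @export
read_beta_matrix <- function(path, check_range = TRUE) {
  dt <- fread_any(path)
  if (ncol(dt) < 2L) stop("matrix file needs an id column plus sample columns")
  ids <- as.character(dt[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate CpG id(s): ", paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in matrix body")
  rownames(m) <- ids
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at CpG %s, sample %s", ids[bad[1L]], colnames(m)[bad[2L]]))
  }
  if (check_range && any(m < 0 | m > 1)) {
    bad <- which(m < 0 | m > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("value %g out of [0,1] at CpG %s, sample %s",
                 m[bad[1L], bad[2L]], ids[bad[1L]], colnames(m)[bad[2L]]))
  }
  m
}

#' Write a matrix as TSV (gzip if the path ends in .gz)
#'
#' @param m matrix with CpG rownames and sample colnames.
#' @param path output path.
#' @param id_col name of the id column in the header.
#' @export
write_beta_matrix <- function(m, path, id_col = "cpg") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' @param path CSV with a `sample_id` column (or first column treated as
#'   such) and phenotype columns.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!"sample_id" %in% names(df)) names(df)[1L] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in sheet")
  if ("group" %in% names(df)) df$group <- as.factor(df$group)
  df
}

#' Read a clock coefficient file
#'
#' Format: comment-style directive header lines `#name=`, `#intercept=`,
#' `#transform=identity|horvath:<adult_age>`, `#units=`, followed by a
#' two-column `cpg,weight` CSV body. See [write_clock_model()] for the
#' writer.
#'
#' @param path coefficient file path.
#' @return a [clock_model()].
#' @export
read_clock_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- sub("^#", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  if (!"intercept" %in% keys) stop("clock file missing '#intercept=' directive")
  name <- if ("name" %in% keys) vals[["name"]] else basename(path)
  tr <- if ("transform" %in% keys) vals[["transform"]] else "identity"
  units <- if ("units" %in% keys) vals[["units"]] else "years"
  adult_age <- NULL
  if (grepl("^horvath:", tr)) {
    adult_age <- as.numeric(sub("^horvath:", "", tr))
    tr <- "horvath"
  } else if (tr != "identity") {
    stop("unknown transform spec '", tr, "'")
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  weights <- numeric(0)
  if (length(body) > 0L) {
    df <- utils::read.csv(text = body, header = grepl("^cpg\\s*,", body[1L]),
                          stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("clock body must be 'cpg,weight' records")
    if (anyDuplicated(df[[1L]]))
      stop("duplicate CpG weight row(s): ",
           paste(utils::head(unique(df[[1L]][duplicated(df[[1L]])]), 5), collapse = ", "))
    weights <- stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
  }
  clock_model(name, intercept = as.numeric(vals[["intercept"]]),
              weights = weights, transform = tr, adult_age = adult_age,
              units = units)
}

#' Write a clock coefficient file
#'
#' @param model a [clock_model()].
#' @param path output path.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  tr <- if (model$transform == "horvath")
    sprintf("horvath:%g", model$adult_age) else "identity"
  hdr <- c(sprintf("#name=%s", model$name),
           sprintf("#intercept=%.17g", model$intercept),
           sprintf("#transform=%s", tr),
           sprintf("#units=%s", model$units),
           "cpg,weight")
  body <- sprintf("%s,%.17g", names(model$weights), model$weights)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits `beta.tsv.gz`, `samples.csv`, `truth.json` and `annotation.tsv`
#' (plus `clock_fixture.csv` when a clock is supplied), the on-disk
#' interchange the pipeline reads back.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param clock optional [clock_model()] fixture to write alongside.
#' @return invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir, clock = NULL) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv.gz"),
             samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.json"),
             annotation = file.path(dir, "annotation.tsv"))
  write_beta_matrix(cohort$beta, paths[["beta"]])
  data.table::fwrite(cohort$samples, paths[["samples"]])
  truth <- cohort$truth
  jsonlite::write_json(
    list(causal_cpgs = truth$causal_cpgs,
         effects = as.list(truth$effects),
         clock_cpgs = truth$clock_cpgs,
         ages = as.list(truth$ages)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  ann <- simulate_annotation(rownames(cohort$beta), seed = cohort$config$seed)
  data.table::fwrite(ann, paths[["annotation"]], sep = "\t")
  if (!is.null(clock)) {
    paths <- c(paths, clock = file.path(dir, "clock_fixture.csv"))
    write_clock_model(clock, paths[["clock"]])
  }
  invisible(paths)
}
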