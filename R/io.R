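# Readers and writers for the package's tabular dialects. One dialect only:
# TSV, UTF-8, '.' decimal, "NA" or empty cells for missing values on input,
# "NA" on output. Nested results go to JSON.

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
}

write_tsv_file <- function(df, path) {
  # 17 significant digits so numeric values round-trip losslessly
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- formatC(df[[j]], digits = 17, format = "g")
      v[is.na(df[[j]])] <- NA
      df[[j]] <- v
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a panel definition file
#'
#' TSV with columns `cell_type` and `markers` (comma-separated ordered marker
#' list), one row per panel.
#'
#' @param path File path.
#' @return A list of [ccce_panel()] objects, named by cell type.
#' @export
read_panel <- function(path) {
  df <- read_tsv_file(path)
  need <- c("cell_type", "markers")
  if (!all(need %in% names(df)))
    stop("panel file must have columns: ", paste(need, collapse = ", "))
  panels <- lapply(seq_len(nrow(df)), function(i) {
    ccce_panel(df$cell_type[i], trimws(strsplit(df$markers[i], ",")[[1]]))
  })
  names(panels) <- df$cell_type
  panels
}

#' Read cohort metadata
#'
#' TSV with columns `individual_id`, `pair_id`, `zygosity` (MZ|DZ), `age`.
#'
#' @param path File path.
#' @return A validated [twin_cohort()].
#' @export
read_cohort <- function(path) {
  df <- read_tsv_file(path)
  need <- c("individual_id", "pair_id", "zygosity", "age")
  if (!all(need %in% names(df)))
    stop("cohort file must have columns: ", paste(need, collapse = ", "))
  twin_cohort(df$individual_id, df$pair_id, df$zygosity, df$age)
}

#' Read a CSF trait table
#'
#' TSV whose first column is `individual_id`; every remaining column is one
#' subpopulation trait (label in the header, values in percent).
#'
#' @param path File path.
#' @return Numeric matrix, individuals x subpopulations.
#' @export
read_csf <- function(path) {
  df <- read_tsv_file(path)
  if (names(df)[1L] != "individual_id")
    stop("first column of a CSF table must be `individual_id`")
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) stop("CSF trait values must be numeric")
  rownames(m) <- as.character(df$individual_id)
  m
}

#' Read a precomputed c2 table
#'
#' TSV with columns `subpopulation` and `c2`; used to bypass the twin variance
#' stage when common-environment fractions come from an external analysis.
#'
#' @param path File path.
#' @return Named numeric vector of c2 values.
#' @export
read_c2_table <- function(path) {
  df <- read_tsv_file(path)
  need <- c("subpopulation", "c2")
  if (!all(need %in% names(df)))
    stop("c2 table must have columns: ", paste(need, collapse = ", "))
  stats::setNames(as.numeric(df$c2), df$subpopulation)
}

#' Load and validate a full dataset from disk
#'
#' Reads the CSF trait table, cohort metadata and panel definition, assembles
#' a validated [csf_dataset()] and logs the counts a user needs to sanity-check
#' an import: individuals, pairs by zygosity, and traits.
#'
#' @param csf_path,meta_path,panel_path File paths (see [read_csf()],
#'   [read_cohort()], [read_panel()]).
#' @param replicate_path Optional replicate table, same shape as the CSF table.
#' @param cell_type When the panel file defines several panels, which one to
#'   use; defaults to the first.
#' @return A [csf_dataset()].
#' @export
load_dataset <- function(csf_path, meta_path, panel_path,
                         replicate_path = NULL, cell_type = NULL) {
  csf <- read_csf(csf_path)
  cohort <- read_cohort(meta_path)
  panels <- read_panel(panel_path)
  panel <- if (is.null(cell_type)) panels[[1L]] else {
    if (!cell_type %in% names(panels))
      stop("cell type '", cell_type, "' not in panel file")
    panels[[cell_type]]
  }
  repl <- if (!is.null(replicate_path)) read_csf(replicate_path) else NULL
  d <- csf_dataset(csf, cohort, panel, replicate = repl)
  nz <- table(cohort$zygosity) / 2
  message("loaded ", panel$cell_type, ": ", nrow(csf), " individuals (",
          nz[["MZ"]], " MZ / ", nz[["DZ"]], " DZ pairs), ", ncol(csf),
          " traits", if (!is.null(repl)) " (+replicates)")
  d
}

#' Write a simulated dataset in the package's TSV dialects
#'
#' Emits `csf.tsv`, `replicate.tsv`, `meta.tsv`, `panel.tsv` and — when the
#' dataset carries a simulation truth — `truth.json`, exactly the files
#' [load_dataset()] consumes.
#'
#' @param dataset A [csf_dataset()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "csf_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_df <- function(m) {
    cbind(data.frame(individual_id = rownames(m), stringsAsFactors = FALSE),
          as.data.frame(m, check.names = FALSE))
  }
  write_tsv_file(as_df(dataset$csf), file.path(dir, "csf.tsv"))
  if (!is.null(dataset$replicate))
    write_tsv_file(as_df(dataset$replicate), file.path(dir, "replicate.tsv"))
  write_tsv_file(as.data.frame(unclass(dataset$cohort)),
                 file.path(dir, "meta.tsv"))
  write_tsv_file(
    data.frame(cell_type = dataset$panel$cell_type,
               markers = paste(dataset$panel$markers, collapse = ","),
               stringsAsFactors = FALSE),
    file.path(dir, "panel.tsv"))
  truth <- attr(dataset, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(cell_type = truth$panel$cell_type,
           markers = truth$panel$markers,
           beta = as.list(truth$beta), c0 = truth$c0,
           noise_sd = truth$noise_sd, age_slope = truth$age_slope,
           c2 = as.list(truth$c2), h2 = as.list(truth$h2),
           e2 = as.list(truth$e2), seed = truth$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Write one CCCE result to disk
#'
#' JSON record (coefficients by marker, chosen parameters, observed error,
#' p-value, FDR if assigned, leading subfunction) plus a TSV with the
#' permutation error vector.
#'
#' @param result A `ccce_result` from [run_ccce_dataset()].
#' @param dir Output directory.
#' @param stem File stem; defaults to the cell type with non-word characters
#'   replaced.
#' @return The JSON path, invisibly.
#' @export
write_ccce_result <- function(result, dir, stem = NULL) {
  stopifnot(inherits(result, "ccce_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(stem)) stem <- gsub("[^A-Za-z0-9._-]+", "_", result$cell_type)
  rec <- list(
    schema = "ccce_result/1",
    cell_type = result$cell_type,
    n_traits = result$n_traits,
    K = result$fit$K,
    penalty = result$fit$penalty,
    mixing = result$fit$mixing,
    intercept = result$fit$intercept,
    coefficients = as.list(result$fit$coefficients),
    prediction_error = result$fit$prediction_error,
    n_perm = result$config$n_perm,
    p_value = result$p_value,
    fdr = if (is.null(result$fdr)) NULL else result$fdr,
    leading = result$leading,
    config = result$config)
  json_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  write_tsv_file(data.frame(perm_error = result$perm_errors),
                 file.path(dir, paste0(stem, "_perm_errors.tsv")))
  if (!is.null(result$components))
    write_tsv_file(result$components,
                   file.path(dir, paste0(stem, "_components.tsv")))
  invisible(json_path)
}

#' Run CCCE across datasets and write all outputs
#'
#' End-to-end orchestration: runs [run_ccce()] over the datasets, writes one
#' JSON + permutation-error TSV per dataset, a cross-dataset `summary.tsv`
#' (cell type, trait count, p, FDR, leading subfunction; sorted by FDR), and
#' the resolved configuration as `config.json`. Reruns with an identical
#' configuration produce identical bytes.
#'
#' @param datasets List of [csf_dataset()] objects.
#' @param out_dir Output directory.
#' @param n_perm,rng_seed,... Passed to [run_ccce()] / [run_ccce_dataset()].
#' @return The `ccce_analysis`, invisibly.
#' @export
ccce_run_all <- function(datasets, out_dir, n_perm = 1000L, rng_seed = 1L,
                         ...) {
  if (n_perm < 1L) stop("config validation: n_perm must be >= 1")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  analysis <- run_ccce(datasets, rng_seed = rng_seed, n_perm = n_perm, ...)
  for (r in analysis$results) write_ccce_result(r, out_dir)
  write_tsv_file(analysis$summary, file.path(out_dir, "summary.tsv"))
  jsonlite::write_json(
    list(schema = "ccce_run/1", n_datasets = length(datasets),
         n_perm = n_perm, rng_seed = rng_seed,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(analysis)
}
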