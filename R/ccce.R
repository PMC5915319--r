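# The CCCE statistic: permutation significance on the cross-validated
# prediction error, leading-subfunction extraction, FDR across datasets, and
# the per-dataset orchestration.

# Deterministic child-seed derivation (kept below 2^31 for R's 32-bit seeds).
derive_seed <- function(master, i) {
  as.integer((as.double(master %% 2147483647L) * 48271 + i * 8191 + 1) %% 2147483647)
}

#' Permutation p-value for the c2-on-subfunction regression
#'
#' The observed statistic is the cross-validated prediction error of the
#' grid-selected elastic net ([select_parameters()]). Each of `n_perm`
#' permutations shuffles the dependent variable c2 across subpopulations
#' (breaking any tie between c2 and the signatures while preserving the
#' internal structure of both) and reruns the FULL selection procedure,
#' including the grid search, with a fresh seeded fold partition. The p-value
#' uses the +1-corrected empirical formula
#' `p = (1 + #\{perm_error <= observed_error\}) / (n_perm + 1)`,
#' which avoids p = 0 and is conservative.
#'
#' @inheritParams select_parameters
#' @param n_perm Number of permutations (the reference analysis uses 1000).
#' @param rng_seed Master seed; per-permutation seeds are derived from it, so
#'   results are identical under sequential or parallel execution.
#' @param cores Permutation replicates run via `parallel::mclapply` when
#'   `cores > 1`.
#' @return List: `p_value`, `perm_errors` (length `n_perm`), `observed` (the
#'   full-data `ccce_fit`).
#' @export
permutation_pvalue <- function(X, y, grid = default_grid(), K, n_perm = 1000L,
                               rng_seed = 1L, cores = 1L) {
  stopifnot(n_perm >= 1L)
  n <- length(y)
  observed <- select_parameters(X, y, grid, K, rng_seed = derive_seed(rng_seed, 0L))
  one_perm <- function(i) {
    ps <- derive_seed(rng_seed, i)
    set.seed(ps)
    yp <- y[sample.int(n)]
    fit <- select_parameters(X, yp, grid, K, rng_seed = derive_seed(ps, 1L),
                             refit = FALSE)
    fit$prediction_error
  }
  perm_errors <- if (cores > 1L) {
    unlist(parallel::mclapply(seq_len(n_perm), one_perm, mc.cores = cores))
  } else {
    vapply(seq_len(n_perm), one_perm, numeric(1))
  }
  p <- (1 + sum(perm_errors <= observed$prediction_error)) / (n_perm + 1)
  list(p_value = p, perm_errors = perm_errors, observed = observed)
}

#' Extract the leading subfunction of a fit
#'
#' The leading subfunction is the marker with the largest absolute fitted
#' coefficient: a positive coefficient links marker PRESENCE with the common
#' environmental effect, a negative one links marker ABSENCE. Exact ties
#' return all tied markers (in panel order) with `tie = TRUE`; an all-zero
#' coefficient vector returns the explicit sentinel `none = TRUE`.
#'
#' @param fit A `ccce_fit` (or a named numeric coefficient vector).
#' @param panel Optional [ccce_panel()] used for marker ordering; defaults to
#'   the coefficient names.
#' @return List: `marker`, `coefficient`, `sign` (`"positive"`/`"negative"`),
#'   `tie`, `none`.
#' @export
leading_subfunction <- function(fit, panel = NULL) {
  beta <- if (inherits(fit, "ccce_fit")) fit$coefficients else fit
  if (is.null(beta)) stop("fit carries no coefficients (refit = FALSE?)")
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "ccce_panel"))
    beta <- beta[panel$markers]
  }
  if (all(beta == 0))
    return(list(marker = character(0), coefficient = numeric(0),
                sign = character(0), tie = FALSE, none = TRUE))
  top <- which(abs(beta) == max(abs(beta)))
  list(marker = names(beta)[top],
       coefficient = unname(beta[top]),
       sign = unname(ifelse(beta[top] > 0, "positive", "negative")),
       tie = length(top) > 1L,
       none = FALSE)
}

#' Benjamini-Hochberg q-values across datasets
#'
#' Step-up false-discovery-rate adjustment of the per-dataset permutation
#' p-values; thresholding the q-values at a level equals the textbook BH
#' rejection set at that level.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return q-values of the same length (empty input gives empty output).
#' @export
fdr_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Run CCCE on one cell-type dataset
#'
#' Full per-dataset pipeline: trait quality control, age adjustment and
#' Falconer decomposition to obtain c2 per subpopulation (skipped when a
#' precomputed c2 table is supplied), the +1/-1 design matrix, cross-validated
#' elastic-net selection, the permutation p-value and the leading subfunction.
#' Fully reproducible given `rng_seed`.
#'
#' @param dataset A [csf_dataset()]; may be `NULL` when `c2` is supplied
#'   together with `panel`.
#' @param c2 Optional precomputed common-environment fractions, a named vector
#'   (names = subpopulation labels) — the pipeline then bypasses the twin
#'   variance stage.
#' @param panel Panel for a precomputed-c2 run; defaults to `dataset$panel`.
#' @param n_perm Number of permutations (default 1000).
#' @param rng_seed Master seed.
#' @param grid Regularization grid ([default_grid()]).
#' @param clamp Clamp negative Falconer components (see
#'   [falconer_decompose()]).
#' @param require_replicate,replicate_threshold,mean_range,min_traits Quality
#'   filter controls (see [qc_filter_traits()] and [qc_filter_dataset()]).
#' @param cores Parallel workers for the permutation loop.
#' @return Object of class `ccce_result`: `cell_type`, `n_traits`, `fit`,
#'   `p_value`, `perm_errors`, `leading`, `components` (per-trait variance
#'   decomposition, `NULL` in precomputed-c2 mode), `c2`, `config`.
#' @export
run_ccce_dataset <- function(dataset = NULL, c2 = NULL, panel = NULL,
                             n_perm = 1000L, rng_seed = 1L,
                             grid = default_grid(), clamp = FALSE,
                             require_replicate = TRUE,
                             replicate_threshold = 0.3,
                             mean_range = c(1, 99), min_traits = 18L,
                             cores = 1L) {
  if (is.null(panel)) {
    if (is.null(dataset)) stop("supply `dataset`, or `c2` with `panel`")
    panel <- dataset$panel
  }
  components <- NULL
  if (!is.null(c2)) {
    if (is.null(names(c2)))
      stop("precomputed c2 must be named by subpopulation label")
    y <- as.numeric(c2)
    labels <- names(c2)
  } else {
    if (is.null(dataset)) stop("supply `dataset`, or `c2` with `panel`")
    qc <- tryCatch(trait_qc(dataset),
                   error = function(e) stop("qc stage: ", conditionMessage(e)))
    keep <- qc_filter_traits(qc, replicate_threshold, mean_range,
                             require_replicate)
    if (!qc_filter_dataset(sum(keep), min_traits))
      stop("dataset fails QC: ", sum(keep), " high-quality traits (need ",
           min_traits, ")")
    kept <- dataset
    kept$csf <- dataset$csf[, keep, drop = FALSE]
    if (!is.null(dataset$replicate))
      kept$replicate <- dataset$replicate[, keep, drop = FALSE]
    components <- tryCatch(
      estimate_components(kept, clamp = clamp),
      error = function(e) stop("variance stage: ", conditionMessage(e)))
    y <- components$c2
    labels <- components$subpopulation
  }
  X <- tryCatch(build_design_matrix(labels, panel),
                error = function(e) stop("design stage: ", conditionMessage(e)))
  K <- choose_fold_count(nrow(X))
  pv <- tryCatch(
    permutation_pvalue(X, y, grid, K, n_perm = n_perm, rng_seed = rng_seed,
                       cores = cores),
    error = function(e) stop("regression stage: ", conditionMessage(e)))
  lead <- leading_subfunction(pv$observed, panel)
  structure(list(cell_type = panel$cell_type,
                 n_traits = nrow(X),
                 fit = pv$observed,
                 p_value = pv$p_value,
                 perm_errors = pv$perm_errors,
                 leading = lead,
                 components = components,
                 c2 = stats::setNames(y, labels),
                 config = list(n_perm = n_perm, rng_seed = rng_seed,
                               clamp = clamp,
                               require_replicate = require_replicate,
                               replicate_threshold = replicate_threshold,
                               mean_range = mean_range,
                               min_traits = min_traits,
                               grid = list(penalty = grid$penalty,
                                           mixing = grid$mixing))),
            class = "ccce_result")
}

#' @export
print.ccce_result <- function(x, ...) {
  cat("<ccce_result> ", x$cell_type, ": ", x$n_traits, " traits, p = ",
      signif(x$p_value, 4), sep = "")
  if (!is.null(x$fdr)) cat(", FDR =", signif(x$fdr, 4))
  cat("\n")
  if (isTRUE(x$leading$none)) {
    cat("leading subfunction: none (all coefficients zero)\n")
  } else {
    cat("leading subfunction: ",
        paste0(x$leading$marker, " (", x$leading$sign, ", ",
               signif(x$leading$coefficient, 4), ")", collapse = "; "),
        if (x$leading$tie) " [tie]", "\n", sep = "")
  }
  invisible(x)
}

#' Run CCCE across a collection of datasets
#'
#' Applies [run_ccce_dataset()] to each dataset, assigns Benjamini-Hochberg
#' FDR across the per-dataset permutation p-values, and returns a summary
#' table sorted by FDR then p-value.
#'
#' @param datasets List of [csf_dataset()] objects (or, in precomputed mode,
#'   a list of lists with elements `c2` and `panel`).
#' @param ... Passed to [run_ccce_dataset()].
#' @param rng_seed Master seed; each dataset gets a derived seed.
#' @return Object of class `ccce_analysis`: `results` (list of `ccce_result`,
#'   with `fdr` filled in) and `summary` (a `data.frame`).
#' @export
run_ccce <- function(datasets, rng_seed = 1L, ...) {
  stopifnot(length(datasets) >= 1L)
  results <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    seed_i <- derive_seed(rng_seed, i)
    results[[i]] <- if (inherits(d, "csf_dataset")) {
      run_ccce_dataset(dataset = d, rng_seed = seed_i, ...)
    } else {
      run_ccce_dataset(c2 = d$c2, panel = d$panel, rng_seed = seed_i, ...)
    }
  }
  q <- fdr_adjust(vapply(results, `[[`, numeric(1), "p_value"))
  for (i in seq_along(results)) results[[i]]$fdr <- q[i]
  lead_chr <- function(r, fld) {
    if (isTRUE(r$leading$none)) return("none")
    paste(r$leading[[fld]], collapse = ";")
  }
  summary <- data.frame(
    cell_type = vapply(results, `[[`, character(1), "cell_type"),
    n_traits = vapply(results, `[[`, numeric(1), "n_traits"),
    K = vapply(results, function(r) r$fit$K, integer(1)),
    p_value = vapply(results, `[[`, numeric(1), "p_value"),
    fdr = q,
    leading_marker = vapply(results, lead_chr, character(1), "marker"),
    leading_sign = vapply(results, lead_chr, character(1), "sign"),
    leading_coefficient = vapply(results, function(r) {
      if (isTRUE(r$leading$none)) NA_real_ else r$leading$coefficient[1L]
    }, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(summary$fdr, summary$p_value, summary$cell_type)
  summary <- summary[ord, , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(results = results[ord], summary = summary),
            class = "ccce_analysis")
}

#' @export
print.ccce_analysis <- function(x, ...) {
  cat("<ccce_analysis> ", length(x$results), " dataset(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}
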