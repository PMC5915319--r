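#' Assemble a CSF trait dataset
#'
#' Bundles one cell type's subpopulation-frequency matrix with its panel and
#' cohort metadata, validating everything the downstream pipeline relies on:
#' each column header parses as a subpopulation label of the panel, every
#' individual appears in the cohort, and (on the percent scale) all
#' frequencies lie in \[0, 100\] — out-of-range values are rejected, never
#' coerced.
#'
#' @param csf Numeric matrix or data.frame, individuals x subpopulations; row
#'   names (or a leading `individual_id` column) are individual ids, column
#'   names are subpopulation labels.
#' @param cohort A [twin_cohort()].
#' @param panel A [ccce_panel()].
#' @param replicate Optional replicate measurement table, same shape as `csf`.
#' @param scale `"percent"` (default; values validated against \[0, 100\]) or
#'   `"liability"` for the simulator's pre-logistic latent scale.
#' @return Object of class `csf_dataset`: list with `csf`, `replicate`,
#'   `cohort`, `panel`, `scale`.
#' @export
csf_dataset <- function(csf, cohort, panel, replicate = NULL,
                        scale = c("percent", "liability")) {
  scale <- match.arg(scale)
  stopifnot(inherits(cohort, "twin_cohort"), inherits(panel, "ccce_panel"))
  as_mat <- function(x, what) {
    if (is.data.frame(x)) {
      if ("individual_id" %in% names(x)) {
        ids <- as.character(x$individual_id)
        x <- as.matrix(x[setdiff(names(x), "individual_id")])
        rownames(x) <- ids
      } else {
        x <- as.matrix(x)
      }
    }
    if (!is.matrix(x) || !is.numeric(x))
      stop(what, " must be a numeric matrix or data.frame")
    if (is.null(rownames(x)))
      stop(what, " must carry individual ids as row names")
    if (is.null(colnames(x)))
      stop(what, " must carry subpopulation labels as column names")
    x
  }
  csf <- as_mat(csf, "`csf`")
  missing_meta <- setdiff(rownames(csf), cohort$individual_id)
  if (length(missing_meta))
    stop("individuals missing from cohort metadata: ",
         paste(missing_meta, collapse = ", "))
  for (lb in colnames(csf)) {
    tryCatch(parse_signature(lb, panel),
             error = function(e) stop("column '", lb, "': ",
                                      conditionMessage(e)))
  }
  if (scale == "percent") {
    v <- csf[!is.na(csf)]
    if (any(v < 0 | v > 100))
      stop("frequencies outside [0, 100]; refusing to coerce")
  }
  if (!is.null(replicate)) {
    replicate <- as_mat(replicate, "`replicate`")
    if (!identical(dim(replicate), dim(csf)) ||
        !identical(colnames(replicate), colnames(csf)))
      stop("`replicate` must have the same shape and labels as `csf`")
    replicate <- replicate[rownames(csf), , drop = FALSE]
  }
  structure(list(csf = csf, replicate = replicate, cohort = cohort,
                 panel = panel, scale = scale),
            class = "csf_dataset")
}

#' @export
print.csf_dataset <- function(x, ...) {
  nz <- table(x$cohort$zygosity) / 2
  cat("<csf_dataset> ", x$panel$cell_type, ": ", nrow(x$csf),
      " individuals (", nz[["MZ"]], " MZ / ", nz[["DZ"]], " DZ pairs), ",
      ncol(x$csf), " subpopulation traits",
      if (!is.null(x$replicate)) " (+replicates)",
      ", scale = ", x$scale, "\n", sep = "")
  invisible(x)
}
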