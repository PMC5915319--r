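#' Define a flow-cytometry marker panel
#'
#' A panel is the ordered set of cell-surface markers measured simultaneously
#' for one cell type. A panel of `k` markers defines up to `2^k` gated cell
#' subpopulations, one per combination of marker presence (+) / absence (-).
#'
#' @param cell_type Free-text label for the gated cell type (e.g. "monocytes").
#' @param markers Character vector of `k` unique marker symbols, in panel
#'   order. Symbols must be non-empty and must not contain `+` or `-` (those
#'   characters delimit markers inside subpopulation labels).
#'
#' @return An object of class `ccce_panel`: a list with elements `cell_type`
#'   and `markers`.
#' @examples
#' ccce_panel("monocytes", c("CD14", "THBD", "CD32"))
#' @export
ccce_panel <- function(cell_type, markers) {
  if (!is.character(cell_type) || length(cell_type) != 1L || is.na(cell_type))
    stop("`cell_type` must be a single character label")
  if (!is.character(markers) || length(markers) < 1L)
    stop("`markers` must be a character vector with at least one symbol")
  if (length(markers) > 16L)
    stop("panels with more than 16 markers are not supported (2^k subpopulations)")
  if (anyNA(markers) || any(!nzchar(markers)))
    stop("marker symbols must be non-empty")
  if (anyDuplicated(markers))
    stop("duplicated marker symbols: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  bad <- grepl("[+−-]", markers, perl = TRUE)
  if (any(bad))
    stop("marker symbols must not contain '+' or '-': ",
         paste(markers[bad], collapse = ", "))
  structure(list(cell_type = cell_type, markers = markers),
            class = "ccce_panel")
}

#' @export
print.ccce_panel <- function(x, ...) {
  cat("<ccce_panel> ", x$cell_type, ": ",
      paste(x$markers, collapse = ", "),
      " (", length(x$markers), " markers, ",
      2^length(x$markers), " subpopulations)\n", sep = "")
  invisible(x)
}

#' Parse a subpopulation label into a marker signature
#'
#' Subpopulation labels follow the usual gating dialect: each panel marker
#' symbol immediately followed by `+` or `-` (the Unicode minus sign
#' \code{"−"} is accepted as a synonym), e.g. `"CD14+THBD-CD32+"`.
#' Every panel marker must appear exactly once; label order is irrelevant,
#' the returned signs are always in panel order.
#'
#' @param label Character label to parse.
#' @param panel A [ccce_panel()].
#' @return Named integer vector of `+1` / `-1`, one entry per panel marker,
#'   in panel order.
#' @examples
#' p <- ccce_panel("t cells", c("A", "B", "C"))
#' parse_signature("C+A+B-", p)
#' @export
parse_signature <- function(label, panel) {
  stopifnot(inherits(panel, "ccce_panel"))
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop("`label` must be a single character string")
  m <- gregexpr("[^+−-]+[+−-]", label, perl = TRUE)
  covered <- if (m[[1]][1] == -1L) 0L else sum(attr(m[[1]], "match.length"))
  if (covered != nchar(label))
    stop("cannot parse subpopulation label '", label,
         "': expected <marker><+|-> tokens covering the whole label")
  tokens <- regmatches(label, m)[[1]]
  syms <- sub("[+−-]$", "", tokens, perl = TRUE)
  sgn <- ifelse(substr(tokens, nchar(tokens), nchar(tokens)) == "+", 1L, -1L)
  unknown <- setdiff(syms, panel$markers)
  if (length(unknown))
    stop("unknown marker token in '", label, "': ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(syms))
    stop("duplicated marker in '", label, "': ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  missing <- setdiff(panel$markers, syms)
  if (length(missing))
    stop("missing marker in '", label, "': ",
         paste(missing, collapse = ", "))
  out <- sgn[match(panel$markers, syms)]
  names(out) <- panel$markers
  out
}

#' Format a marker signature as a subpopulation label
#'
#' Inverse of [parse_signature()]: markers are emitted in panel order with
#' ASCII `+` / `-` suffixes, so `parse_signature(format_signature(s, p), p)`
#' is the identity.
#'
#' @param signs Vector of `+1` / `-1`, one per panel marker, in panel order.
#' @param panel A [ccce_panel()].
#' @return A single character label.
#' @export
format_signature <- function(signs, panel) {
  stopifnot(inherits(panel, "ccce_panel"))
  k <- length(panel$markers)
  if (length(signs) != k || !all(signs %in% c(-1, 1)))
    stop("`signs` must be a length-", k, " vector of +1/-1")
  paste0(panel$markers, ifelse(signs > 0, "+", "-"), collapse = "")
}

#' Enumerate all subpopulations of a panel
#'
#' Returns the full factorial of marker presence/absence: exactly `2^k`
#' distinct signatures in lexicographic order over the sign vector with `+`
#' before `-` (the first marker varies slowest), so output order is
#' byte-reproducible.
#'
#' @param panel A [ccce_panel()].
#' @return Integer matrix with `2^k` rows and `k` columns of `+1` / `-1`;
#'   column names are the panel markers, row names the formatted labels.
#' @examples
#' enumerate_subpopulations(ccce_panel("nk", c("CD2", "CD57")))
#' @export
enumerate_subpopulations <- function(panel) {
  stopifnot(inherits(panel, "ccce_panel"))
  k <- length(panel$markers)
  n <- 2L^k
  m <- matrix(1L, n, k)
  for (j in seq_len(k)) {
    block <- 2L^(k - j)
    m[, j] <- ifelse((((seq_len(n) - 1L) %/% block) %% 2L) == 0L, 1L, -1L)
  }
  colnames(m) <- panel$markers
  rownames(m) <- apply(m, 1L, format_signature, panel = panel)
  m
}

#' Build the +1/-1 subfunction design matrix
#'
#' Each included subpopulation (CSF trait) contributes one row; each panel
#' marker one column. Entry (i, j) is +1 when subpopulation i carries marker
#' j, else -1. This is the predictor matrix of the c2-on-subfunction
#' regression, so duplicate signatures are an error (they would double-weight
#' a subpopulation).
#'
#' @param signatures Either a matrix of `+1`/`-1` (rows = subpopulations,
#'   columns in panel order) or a character vector of subpopulation labels to
#'   be parsed against the panel.
#' @param panel A [ccce_panel()].
#' @return Numeric matrix with marker column names and label row names; row
#'   order preserves the input order.
#' @export
build_design_matrix <- function(signatures, panel) {
  stopifnot(inherits(panel, "ccce_panel"))
  k <- length(panel$markers)
  if (is.character(signatures)) {
    m <- t(vapply(signatures, parse_signature, integer(k), panel = panel))
    rownames(m) <- signatures
  } else if (is.matrix(signatures)) {
    if (ncol(signatures) != k)
      stop("signature matrix must have one column per panel marker")
    if (!all(signatures %in% c(-1, 1)))
      stop("signature entries must be +1 or -1")
    m <- signatures
    if (is.null(rownames(m)))
      rownames(m) <- apply(m, 1L, format_signature, panel = panel)
  } else {
    stop("`signatures` must be a +1/-1 matrix or a character vector of labels")
  }
  if (nrow(m) > 2^k)
    stop("more signatures than the 2^k subpopulations of the panel")
  if (anyDuplicated(m, MARGIN = 1L)) {
    dup <- rownames(m)[duplicated(m, MARGIN = 1L)]
    stop("duplicate subpopulation signatures: ",
         paste(unique(dup), collapse = ", "))
  }
  storage.mode(m) <- "double"
  colnames(m) <- panel$markers
  m
}
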