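#' Construct a twin-cohort metadata table
#'
#' @param individual_id Character ids, one per individual.
#' @param pair_id Character pair/family ids; each pair id must map to exactly
#'   two individuals of the same zygosity.
#' @param zygosity `"MZ"` or `"DZ"` per individual.
#' @param age Age in years (non-negative, finite).
#' @return A `data.frame` of class `twin_cohort`.
#' @export
twin_cohort <- function(individual_id, pair_id, zygosity, age) {
  individual_id <- as.character(individual_id)
  pair_id <- as.character(pair_id)
  zygosity <- as.character(zygosity)
  age <- as.numeric(age)
  n <- length(individual_id)
  if (length(pair_id) != n || length(zygosity) != n || length(age) != n)
    stop("cohort columns must have equal length")
  if (anyDuplicated(individual_id))
    stop("duplicated individual ids: ",
         paste(unique(individual_id[duplicated(individual_id)]), collapse = ", "))
  bad <- !zygosity %in% c("MZ", "DZ")
  if (any(bad))
    stop("malformed zygosity values (expected MZ or DZ): ",
         paste(unique(zygosity[bad]), collapse = ", "))
  if (anyNA(age) || any(!is.finite(age)) || any(age < 0))
    stop("ages must be non-negative finite numbers")
  sizes <- table(pair_id)
  if (any(sizes != 2L))
    stop("every pair must have exactly 2 members; offending pair ids: ",
         paste(names(sizes)[sizes != 2L], collapse = ", "))
  zyg_per_pair <- tapply(zygosity, pair_id, function(z) length(unique(z)))
  if (any(zyg_per_pair != 1L))
    stop("zygosity differs within pair(s): ",
         paste(names(zyg_per_pair)[zyg_per_pair != 1L], collapse = ", "))
  structure(
    data.frame(individual_id = individual_id, pair_id = pair_id,
               zygosity = zygosity, age = age, stringsAsFactors = FALSE),
    class = c("twin_cohort", "data.frame"))
}

#' Remove the linear age effect from a trait
#'
#' Fits ordinary least squares `value ~ age` pooled across all individuals and
#' returns the residuals with the trait mean added back, so adjusted values
#' stay on the original (percent) scale. Individuals missing either the trait
#' value or the age are dropped.
#'
#' @param values Named numeric vector of trait values (names = individual ids).
#' @param cohort A [twin_cohort()].
#' @return Named numeric vector of age-adjusted values for the usable
#'   individuals.
#' @export
adjust_for_age <- function(values, cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (is.null(names(values)))
    stop("`values` must be named by individual id")
  idx <- match(names(values), cohort$individual_id)
  if (anyNA(idx))
    stop("individuals absent from cohort metadata: ",
         paste(names(values)[is.na(idx)], collapse = ", "))
  age <- cohort$age[idx]
  use <- !is.na(values) & !is.na(age)
  v <- as.numeric(values[use]); a <- age[use]
  if (length(v) < 3L)
    stop("fewer than 3 usable individuals for age adjustment")
  if (length(unique(a)) == 1L)
    stop("age effect unidentifiable: all ages identical")
  fit <- stats::lm(v ~ a)
  out <- as.numeric(stats::residuals(fit)) + mean(v)
  names(out) <- names(values)[use]
  out
}

#' Double-entry twin-pair correlation
#'
#' Pearson correlation across complete pairs of the requested zygosity, with
#' each pair (a, b) entered in both orderings (a, b) and (b, a). Double entry
#' removes the arbitrary labelling of "twin 1" vs "twin 2" and equals the
#' usual moment intraclass correlation in expectation. Pairs with a missing
#' member are excluded entirely.
#'
#' @param values Named numeric vector (names = individual ids).
#' @param cohort A [twin_cohort()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return A single correlation in \[-1, 1\].
#' @export
pair_correlation <- function(values, cohort, zygosity = c("MZ", "DZ")) {
  stopifnot(inherits(cohort, "twin_cohort"))
  zygosity <- match.arg(zygosity)
  sub <- cohort[cohort$zygosity == zygosity, , drop = FALSE]
  pairs <- split(sub$individual_id, sub$pair_id)
  v1 <- v2 <- numeric(0)
  for (ids in pairs) {
    a <- values[ids[1L]]; b <- values[ids[2L]]
    if (is.na(a) || is.na(b)) next
    v1 <- c(v1, a); v2 <- c(v2, b)
  }
  if (length(v1) < 2L)
    stop("undefined correlation: fewer than 2 complete ", zygosity, " pairs")
  x <- c(v1, v2); y <- c(v2, v1)
  if (stats::sd(x) == 0)
    stop("undefined correlation: zero variance among ", zygosity, " pair members")
  stats::cor(x, y)
}

#' Falconer variance decomposition
#'
#' The moment estimator comparing monozygotic twins (shared genetics, shared
#' family environment) with dizygotic twins (half the segregating genetics,
#' shared family environment):
#' \deqn{h^2 = 2(r_{mz} - r_{dz}), \quad c^2 = 2 r_{dz} - r_{mz}, \quad
#'       e^2 = V_p - h^2 - c^2.}
#' Raw (possibly negative) estimates are returned by default; they are
#' legitimate moment estimates and clamping them silently would hide signal.
#' With `clamp = TRUE`, components are truncated at 0 and rescaled to sum to
#' `V_p`.
#'
#' @param r_mz,r_dz Twin correlations in \[-1, 1\] (vectorized).
#' @param V_p Total phenotypic variance of the (age-adjusted) trait; the
#'   default 1 corresponds to traits standardized to unit variance, so the
#'   components are fractions.
#' @param clamp Truncate negative components at zero and renormalize.
#' @return A `data.frame` with columns `r_mz`, `r_dz`, `h2`, `c2`, `e2`,
#'   `V_p` (and `clamped` when `clamp = TRUE`).
#' @examples
#' falconer_decompose(0.8, 0.5)
#' @export
falconer_decompose <- function(r_mz, r_dz, V_p = 1, clamp = FALSE) {
  if (anyNA(r_mz) || anyNA(r_dz) || any(!is.finite(r_mz)) || any(!is.finite(r_dz)))
    stop("non-finite twin correlations")
  if (any(r_mz < -1 | r_mz > 1) || any(r_dz < -1 | r_dz > 1))
    stop("twin correlations must lie in [-1, 1]")
  if (any(!is.finite(V_p)) || any(V_p <= 0))
    stop("V_p must be positive and finite")
  n <- max(length(r_mz), length(r_dz), length(V_p))
  r_mz <- rep_len(r_mz, n); r_dz <- rep_len(r_dz, n); V_p <- rep_len(V_p, n)
  h2 <- 2 * (r_mz - r_dz)
  c2 <- 2 * r_dz - r_mz
  e2 <- V_p - h2 - c2
  out <- data.frame(r_mz = r_mz, r_dz = r_dz, h2 = h2, c2 = c2, e2 = e2,
                    V_p = V_p)
  if (clamp) {
    comp <- pmax(cbind(h2, c2, e2), 0)
    tot <- rowSums(comp)
    scale <- ifelse(tot > 0, V_p / tot, 0)
    out$clamped <- (h2 < 0) | (c2 < 0) | (e2 < 0)
    out$h2 <- comp[, 1] * scale
    out$c2 <- comp[, 2] * scale
    out$e2 <- comp[, 3] * scale
  }
  out
}

#' Per-trait quality statistics
#'
#' Mean trait value (percent) and, when a replicate table is present, the
#' Pearson correlation between the two replicate measurements across
#' individuals.
#'
#' @param dataset A [csf_dataset()].
#' @return `data.frame` with columns `subpopulation`, `mean_value`,
#'   `replicate_correlation` (`NA` when no replicate is available).
#' @export
trait_qc <- function(dataset) {
  stopifnot(inherits(dataset, "csf_dataset"))
  mv <- colMeans(dataset$csf, na.rm = TRUE)
  if (is.null(dataset$replicate)) {
    rc <- rep(NA_real_, ncol(dataset$csf))
  } else {
    rc <- vapply(seq_len(ncol(dataset$csf)), function(j) {
      x <- dataset$csf[, j]; y <- dataset$replicate[, j]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(NA_real_)
      stats::cor(x[ok], y[ok])
    }, numeric(1))
  }
  data.frame(subpopulation = colnames(dataset$csf), mean_value = mv,
             replicate_correlation = rc, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Trait-level quality filter
#'
#' Keeps high-quality CSF traits: replicate correlation strictly above
#' `replicate_threshold` and mean trait value inside `mean_range` (inclusive).
#' Traits without a replicate correlation pass the replicate criterion only
#' when `require_replicate = FALSE`.
#'
#' @param stats A `data.frame` as returned by [trait_qc()].
#' @param replicate_threshold Strict lower bound on replicate correlation
#'   (default 0.3).
#' @param mean_range Inclusive bounds on the mean trait value in percent
#'   (default `c(1, 99)`).
#' @param require_replicate Drop traits lacking a replicate correlation.
#' @return Logical keep vector, one entry per row of `stats`.
#' @export
qc_filter_traits <- function(stats, replicate_threshold = 0.3,
                             mean_range = c(1, 99), require_replicate = TRUE) {
  rc <- stats$replicate_correlation
  rep_ok <- !is.na(rc) & rc > replicate_threshold
  if (!require_replicate) rep_ok <- rep_ok | is.na(rc)
  mean_ok <- !is.na(stats$mean_value) &
    stats$mean_value >= mean_range[1] & stats$mean_value <= mean_range[2]
  rep_ok & mean_ok
}

#' Dataset-level quality filter
#'
#' A cell-type dataset is analyzable only when it retains at least
#' `min_traits` high-quality CSF traits (default 18).
#'
#' @param n_kept_traits Number of traits surviving [qc_filter_traits()].
#' @param min_traits Minimum trait count.
#' @return `TRUE` iff the dataset passes.
#' @export
qc_filter_dataset <- function(n_kept_traits, min_traits = 18L) {
  stopifnot(length(n_kept_traits) == 1L, n_kept_traits >= 0)
  n_kept_traits >= min_traits
}

#' Estimate variance components for every trait of a dataset
#'
#' For each CSF trait: adjust for age ([adjust_for_age()]), optionally
#' standardize to unit variance (so the components are fractions and c2 is
#' directly the regression target), compute double-entry MZ and DZ pair
#' correlations, and apply [falconer_decompose()].
#'
#' @param dataset A [csf_dataset()].
#' @param standardize Standardize age-adjusted traits to unit variance
#'   (default). With `FALSE`, `V_p` is the raw variance of the age-adjusted
#'   trait.
#' @param clamp Passed to [falconer_decompose()].
#' @param adjust_age Set `FALSE` to skip age adjustment (e.g. ages absent by
#'   construction).
#' @return `data.frame` with one row per trait: `subpopulation`, `n_mz`,
#'   `n_dz` (complete pairs), `r_mz`, `r_dz`, `h2`, `c2`, `e2`, `V_p`.
#' @export
estimate_components <- function(dataset, standardize = TRUE, clamp = FALSE,
                                adjust_age = TRUE) {
  stopifnot(inherits(dataset, "csf_dataset"))
  cohort <- dataset$cohort
  labs <- colnames(dataset$csf)
  rows <- lapply(labs, function(lb) {
    v <- dataset$csf[, lb]
    names(v) <- rownames(dataset$csf)
    if (adjust_age) v <- adjust_for_age(v, cohort)
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0)
      stop("trait '", lb, "' has zero variance after age adjustment")
    if (standardize) {
      v <- (v - mean(v, na.rm = TRUE)) / s
      vp <- 1
    } else {
      vp <- s^2
    }
    rmz <- pair_correlation(v, cohort, "MZ")
    rdz <- pair_correlation(v, cohort, "DZ")
    fc <- falconer_decompose(rmz, rdz, V_p = vp, clamp = clamp)
    n_complete <- function(z) {
      sub <- cohort[cohort$zygosity == z, , drop = FALSE]
      sum(vapply(split(sub$individual_id, sub$pair_id),
                 function(ids) !anyNA(v[ids]), logical(1)))
    }
    cbind(data.frame(subpopulation = lb, n_mz = n_complete("MZ"),
                     n_dz = n_complete("DZ"), stringsAsFactors = FALSE),
          fc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
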