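# Elastic-net machinery: regularization grid, seeded folds, cross-validated
# prediction error, and grid selection. The coordinate-descent solver lives in
# src/enet.cpp; everything here is orchestration.

#' Regularization grid for the c2-on-subfunction elastic net
#'
#' Default: 20 log-spaced penalty strengths in \[1e-3, 10\] crossed with
#' mixing weights (0.1, 0.5, 0.9, 1), spanning ridge-like to lasso fits.
#' The mixing weight is the lasso fraction of the penalty:
#' `penalty * (mixing * L1 + (1 - mixing)/2 * L2)`.
#'
#' @param penalty Positive penalty strengths.
#' @param mixing Mixing weights in (0, 1].
#' @return List of class `ccce_grid` with elements `penalty` and `mixing`.
#' @export
default_grid <- function(penalty = 10^seq(log10(1e-3), log10(10), length.out = 20),
                         mixing = c(0.1, 0.5, 0.9, 1)) {
  if (length(penalty) == 0L || length(mixing) == 0L)
    stop("regularization grid must be non-empty")
  if (any(!is.finite(penalty)) || any(penalty <= 0))
    stop("penalty strengths must be strictly positive")
  if (any(!is.finite(mixing)) || any(mixing <= 0) || any(mixing > 1))
    stop("mixing weights must lie in (0, 1]")
  structure(list(penalty = sort(unique(penalty)), mixing = sort(unique(mixing))),
            class = "ccce_grid")
}

#' Cross-validation fold count
#'
#' K is the number of CSF traits divided by 5 (floored, never below 2): many
#' folds while keeping at least five subpopulations per fold.
#'
#' @param n_traits Number of CSF traits entering the regression.
#' @return Integer fold count.
#' @examples
#' choose_fold_count(30) # 6
#' @export
choose_fold_count <- function(n_traits) {
  stopifnot(length(n_traits) == 1L, is.finite(n_traits))
  if (n_traits < 10)
    stop("too few traits for cross-validation (need at least 10)")
  max(2L, as.integer(floor(n_traits / 5)))
}

# Seeded near-equal fold assignment (sizes differ by at most 1).
make_folds <- function(n, K, rng_seed) {
  if (K < 2L || K > n) stop("K must satisfy 2 <= K <= n")
  set.seed(rng_seed)
  sample(rep_len(seq_len(K), n))
}

# Fit the elastic-net path on one training set; returns k x L beta matrix and
# intercepts for a non-increasing lambda path.
enet_path <- function(X, y, lambda_desc, mixing, tol = 1e-9, max_iter = 100000L) {
  .enet_path_cd(X, as.numeric(y), as.numeric(lambda_desc), mixing, tol,
                as.integer(max_iter))
}

#' Fit the elastic net on all rows at one grid point
#'
#' Minimizes `(1/2n) * RSS + penalty * (mixing * ||b||_1 +
#' (1 - mixing)/2 * ||b||_2^2)` with an unpenalized intercept and
#' unstandardized predictors (the +1/-1 codes are already balanced).
#'
#' @param X Design matrix from [build_design_matrix()].
#' @param y Response (c2 per subpopulation).
#' @param penalty,mixing Elastic-net parameters.
#' @param tol,max_iter Coordinate-descent convergence controls.
#' @return List with `coefficients` (named by marker) and `intercept`.
#' @export
enet_fit <- function(X, y, penalty, mixing, tol = 1e-9, max_iter = 100000L) {
  stopifnot(nrow(X) == length(y), length(penalty) == 1L, penalty >= 0,
            length(mixing) == 1L, mixing > 0, mixing <= 1)
  if (any(!is.finite(y))) stop("non-finite response values")
  # short warm-up path improves convergence at small penalties
  path <- sort(unique(c(penalty * c(1000, 100, 10), penalty)), decreasing = TRUE)
  fit <- enet_path(X, y, path, mixing, tol, max_iter)
  j <- length(path)
  beta <- fit$beta[, j]
  names(beta) <- colnames(X)
  list(coefficients = beta, intercept = fit$intercept[j])
}

# Mean K-fold held-out squared error for every (penalty, mixing) grid point,
# sharing one fold partition across the grid. Returns a matrix
# length(penalty) x length(mixing) with penalties in DECREASING order
# (dimnames carry the values).
cv_grid_errors <- function(X, y, folds, grid, tol = 1e-9, max_iter = 100000L) {
  lam_desc <- sort(grid$penalty, decreasing = TRUE)
  K <- max(folds)
  err <- matrix(0, length(lam_desc), length(grid$mixing),
                dimnames = list(format(lam_desc, digits = 10),
                                format(grid$mixing, digits = 10)))
  for (f in seq_len(K)) {
    test <- folds == f
    Xtr <- X[!test, , drop = FALSE]; ytr <- y[!test]
    Xte <- X[test, , drop = FALSE]; yte <- y[test]
    for (m in seq_along(grid$mixing)) {
      fit <- enet_path(Xtr, ytr, lam_desc, grid$mixing[m], tol, max_iter)
      pred <- sweep(Xte %*% fit$beta, 2L, fit$intercept, "+")
      err[, m] <- err[, m] + colMeans((pred - yte)^2)
    }
  }
  err / K
}

#' Cross-validated prediction error at one grid point
#'
#' Partitions the subpopulations into K near-equal folds by a seeded shuffle;
#' for each fold the elastic net is trained on the other K-1 folds and the
#' mean squared error is computed on the held-out fold. Returns the mean of
#' the K fold errors.
#'
#' @inheritParams enet_fit
#' @param K Fold count (see [choose_fold_count()]).
#' @param rng_seed Seed for the fold shuffle.
#' @return Mean held-out squared error (a single number).
#' @export
cv_prediction_error <- function(X, y, penalty, mixing, K, rng_seed,
                                tol = 1e-9, max_iter = 100000L) {
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(y))) stop("non-finite response values")
  folds <- make_folds(length(y), K, rng_seed)
  grid <- list(penalty = penalty, mixing = mixing)
  as.numeric(cv_grid_errors(X, y, folds, grid, tol, max_iter))
}

#' Select elastic-net parameters by K-fold cross-validation
#'
#' Evaluates [cv_prediction_error()] for every grid point with the SAME seeded
#' fold partition (so grid points are compared on identical splits), picks the
#' arg-min — ties broken toward the larger penalty, then the larger mixing
#' weight (the sparser model) — and refits on all rows at the chosen point.
#'
#' @inheritParams cv_prediction_error
#' @param grid A [default_grid()].
#' @param refit Set `FALSE` to skip the final full-data refit (used inside the
#'   permutation loop where only the prediction error is needed).
#' @return Object of class `ccce_fit`: `coefficients`, `intercept`, `penalty`,
#'   `mixing`, `prediction_error`, `K`, and the full `cv_errors` matrix.
#' @export
select_parameters <- function(X, y, grid = default_grid(), K, rng_seed,
                              refit = TRUE, tol = 1e-9, max_iter = 100000L) {
  stopifnot(inherits(grid, "ccce_grid") || is.list(grid))
  if (length(grid$penalty) == 0L || length(grid$mixing) == 0L)
    stop("empty regularization grid")
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(y))) stop("non-finite response values")
  folds <- make_folds(length(y), K, rng_seed)
  err <- cv_grid_errors(X, y, folds, grid, tol, max_iter)
  # rows are in decreasing penalty order: first index = largest penalty;
  # ties -> smallest row index, then largest column index (largest mixing)
  hits <- which(err == min(err), arr.ind = TRUE)
  r <- min(hits[, 1L])
  c <- max(hits[hits[, 1L] == r, 2L])
  lam_desc <- sort(grid$penalty, decreasing = TRUE)
  chosen_penalty <- lam_desc[r]
  chosen_mixing <- grid$mixing[c]
  out <- list(penalty = chosen_penalty, mixing = chosen_mixing,
              prediction_error = err[r, c], K = as.integer(K),
              cv_errors = err, coefficients = NULL, intercept = NULL)
  if (refit) {
    full <- enet_fit(X, y, chosen_penalty, chosen_mixing, tol, max_iter)
    out$coefficients <- full$coefficients
    out$intercept <- full$intercept
  }
  class(out) <- "ccce_fit"
  out
}

#' @export
print.ccce_fit <- function(x, ...) {
  cat("<ccce_fit> penalty =", signif(x$penalty, 4),
      " mixing =", x$mixing,
      " K =", x$K,
      " CV error =", signif(x$prediction_error, 4), "\n")
  if (!is.null(x$coefficients)) {
    cat("coefficients:\n")
    print(round(x$coefficients, 4))
  }
  invisible(x)
}
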