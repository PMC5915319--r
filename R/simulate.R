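# Seeded twin-cohort simulator with planted ACE variance components. The
# planted common-environment fraction is a linear function of the marker
# signature — the ground truth every calibration and recovery test runs
# against.

#' Plant per-subpopulation variance components
#'
#' Builds the simulation ground truth for a panel: for every subpopulation
#' `s` with signature `x_s`, the planted common-environment fraction is
#' `c2_s = clip(c0 + sum_j beta_j * x_sj + eta_s, 0.02, 0.9)` with
#' `eta_s ~ N(0, noise_sd)`. Heritabilities are drawn uniformly in
#' \[0.1, 0.6\] subject to `h2_s + c2_s <= 0.95`, and `e2_s = 1 - h2_s - c2_s`,
#' so all three components stay strictly positive. The clip bounds keep the
#' regression target inside (0, 1).
#'
#' @param panel A [ccce_panel()].
#' @param beta Length-k signature-effect vector on c2 (one entry per marker).
#' @param c0 Baseline c2 (intercept of the planted linear model).
#' @param noise_sd Standard deviation of the per-subpopulation perturbation
#'   `eta_s`.
#' @param seed Seed; the truth is deterministic given it.
#' @param h2 Optional fixed heritability (scalar or per-subpopulation vector)
#'   instead of the uniform draw — used by estimator-recovery studies that
#'   need an exact planted value.
#' @param age_slope Linear age effect added to the trait liability, per year.
#' @return Object of class `sim_truth`: panel, planted `beta`, `c0`,
#'   `noise_sd`, `age_slope`, the signature matrix, per-subpopulation `c2`,
#'   `h2`, `e2`, logistic `baseline` offsets, and the seed.
#' @examples
#' p <- ccce_panel("sim", c("A", "B", "C"))
#' plant_effects(p, beta = c(0.2, 0, 0), c0 = 0.3, noise_sd = 0, seed = 1)
#' @export
plant_effects <- function(panel, beta, c0, noise_sd = 0.05, seed = 1L,
                          h2 = NULL, age_slope = 0.01) {
  stopifnot(inherits(panel, "ccce_panel"))
  k <- length(panel$markers)
  if (length(beta) != k) stop("`beta` must have one entry per panel marker")
  if (!is.finite(c0) || any(!is.finite(beta))) stop("non-finite effects")
  if (c0 + sum(abs(beta)) >= 1)
    stop("infeasible configuration: c0 + sum(|beta|) must be < 1")
  sig <- enumerate_subpopulations(panel)
  n_s <- nrow(sig)
  set.seed(seed)
  eta <- if (noise_sd > 0) stats::rnorm(n_s, 0, noise_sd) else numeric(n_s)
  c2_lin <- c0 + as.numeric(sig %*% beta) + eta
  c2 <- pmin(pmax(c2_lin, 0.02), 0.9)
  n_clip <- sum(c2 != c2_lin)
  if (n_clip > 0.1 * n_s)
    warning(n_clip, " of ", n_s, " planted c2 values clipped to [0.02, 0.9]")
  if (is.null(h2)) {
    ub <- pmin(0.6, 0.95 - c2)
    lb <- pmin(0.1, ub)
    h2 <- lb + stats::runif(n_s) * (ub - lb)
  } else {
    h2 <- rep_len(h2, n_s)
    if (any(h2 < 0) || any(h2 + c2 > 0.95))
      stop("fixed h2 violates h2_s + c2_s <= 0.95")
  }
  e2 <- 1 - h2 - c2
  baseline <- stats::runif(n_s, -1.5, 1.5)
  structure(list(panel = panel, beta = stats::setNames(beta, panel$markers),
                 c0 = c0, noise_sd = noise_sd, age_slope = age_slope,
                 signatures = sig,
                 c2 = stats::setNames(c2, rownames(sig)),
                 h2 = stats::setNames(h2, rownames(sig)),
                 e2 = stats::setNames(e2, rownames(sig)),
                 baseline = stats::setNames(baseline, rownames(sig)),
                 seed = as.integer(seed)),
            class = "sim_truth")
}

#' Simulate a twin cohort under a planted ACE model
#'
#' For each subpopulation and twin pair, draws the three latent components of
#' the classical additive model: A (additive genetic — identical within MZ
#' pairs, correlation exactly 0.5 within DZ pairs via a shared + unique
#' split), C (identical within every pair) and E (independent per individual),
#' each standard normal and scaled by `sqrt(h2_s)`, `sqrt(c2_s)`,
#' `sqrt(e2_s)`. Ages are uniform on \[20, 70\], shared within a pair, and
#' enter the liability linearly. On the default percent scale, liabilities are
#' mapped through `100 * plogis(baseline_s + 0.5 * liability)`, a mild
#' monotone nonlinearity around subpopulation-specific baselines; replicates
#' add independent measurement noise on the liability scale calibrated to a
#' replicate correlation of about 0.9.
#'
#' @param truth A [plant_effects()] object.
#' @param n_mz_pairs,n_dz_pairs Number of pairs per zygosity (each >= 2).
#' @param seed Seed; all outputs are reproducible from `(truth, seed)`.
#' @param scale `"percent"` for the logistic-mapped frequency scale,
#'   `"liability"` for the raw latent scale (used by estimator-recovery
#'   studies, which avoid the logistic attenuation).
#' @return A [csf_dataset()] (with replicates) carrying `truth` as an
#'   attribute.
#' @export
simulate_cohort <- function(truth, n_mz_pairs, n_dz_pairs, seed = 1L,
                            scale = c("percent", "liability")) {
  stopifnot(inherits(truth, "sim_truth"))
  scale <- match.arg(scale)
  if (n_mz_pairs < 2L || n_dz_pairs < 2L)
    stop("need at least 2 pairs per zygosity")
  n_pairs <- n_mz_pairs + n_dz_pairs
  n_ind <- 2L * n_pairs
  pair_zyg <- rep(c("MZ", "DZ"), c(n_mz_pairs, n_dz_pairs))
  pair_id <- sprintf("%s%04d", pair_zyg, c(seq_len(n_mz_pairs), seq_len(n_dz_pairs)))
  ind_id <- paste0(rep(pair_id, each = 2L), "-", rep(1:2, n_pairs))

  set.seed(seed)
  age_pair <- stats::runif(n_pairs, 20, 70)
  age <- rep(age_pair, each = 2L)
  cohort <- twin_cohort(ind_id, rep(pair_id, each = 2L),
                        rep(pair_zyg, each = 2L), age)

  sig <- truth$signatures
  n_s <- nrow(sig)
  is_mz <- rep(pair_zyg == "MZ", each = 2L)
  # age contribution centered so the liability stays near mean zero
  age_term <- truth$age_slope * (age - mean(c(20, 70)))

  liab <- matrix(0, n_ind, n_s, dimnames = list(ind_id, rownames(sig)))
  rep_noise_sd <- sqrt(1 / 0.81 - 1) # replicate correlation ~0.9 on liability
  rep_liab <- liab
  for (s in seq_len(n_s)) {
    A_shared <- rep(stats::rnorm(n_pairs), each = 2L)
    A_unique <- stats::rnorm(n_ind)
    A <- ifelse(is_mz, A_shared,
                sqrt(0.5) * A_shared + sqrt(0.5) * A_unique)
    C <- rep(stats::rnorm(n_pairs), each = 2L)
    E <- stats::rnorm(n_ind)
    x <- sqrt(truth$h2[s]) * A + sqrt(truth$c2[s]) * C +
      sqrt(truth$e2[s]) * E + age_term
    liab[, s] <- x
    rep_liab[, s] <- x + stats::rnorm(n_ind, 0, rep_noise_sd)
  }

  if (scale == "percent") {
    values <- 100 * stats::plogis(sweep(0.5 * liab, 2L, truth$baseline, "+"))
    repl <- 100 * stats::plogis(sweep(0.5 * rep_liab, 2L, truth$baseline, "+"))
  } else {
    values <- liab
    repl <- rep_liab
  }
  out <- csf_dataset(values, cohort, truth$panel, replicate = repl,
                     scale = scale)
  attr(out, "truth") <- truth
  out
}

#' Simulate a null cohort (c2 unrelated to signatures)
#'
#' Convenience wrapper around [plant_effects()] + [simulate_cohort()] with a
#' zero signature-effect vector and heterogeneous per-subpopulation c2 (noise
#' only), so the common-environment fractions vary but carry no subfunction
#' signal — the calibration target for the permutation p-value.
#'
#' @inheritParams simulate_cohort
#' @param panel A [ccce_panel()].
#' @param c0 Baseline c2.
#' @param noise_sd Spread of the per-subpopulation c2 around `c0`.
#' @param scale Passed to [simulate_cohort()].
#' @return A [csf_dataset()] with a null `truth` attribute.
#' @export
simulate_null <- function(panel, n_mz_pairs, n_dz_pairs, seed = 1L,
                          c0 = 0.3, noise_sd = 0.1,
                          scale = c("percent", "liability")) {
  truth <- plant_effects(panel, beta = rep(0, length(panel$markers)),
                         c0 = c0, noise_sd = noise_sd,
                         seed = derive_seed(seed, 0L))
  simulate_cohort(truth, n_mz_pairs, n_dz_pairs,
                  seed = derive_seed(seed, 1L), scale = scale)
}
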