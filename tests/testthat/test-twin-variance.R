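make_cohort <- function(n_mz = 4, n_dz = 4, age = NULL) {
  n <- n_mz + n_dz
  pid <- sprintf("P%02d", rep(seq_len(n), each = 2))
  zyg <- rep(rep(c("MZ", "DZ"), c(n_mz, n_dz)), each = 2)
  if (is.null(age)) age <- seq(20, 70, length.out = 2 * n)
  twin_cohort(paste0(pid, "-", rep(1:2, n)), pid, zyg, age)
}

test_that("cohort metadata invariants are enforced", {
  expect_error(twin_cohort(c("a", "b", "c"), c("p1", "p1", "p1"),
                           c("MZ", "MZ", "MZ"), c(30, 30, 30)),
               "exactly 2 members")
  expect_error(twin_cohort(c("a", "b"), c("p1", "p1"), c("MZ", "DZ"),
                           c(30, 30)),
               "zygosity differs")
  expect_error(twin_cohort(c("a", "b"), c("p1", "p1"), c("MZ", "mz"),
                           c(30, 30)),
               "malformed zygosity")
  expect_error(twin_cohort(c("a", "b"), c("p1", "p1"), c("MZ", "MZ"),
                           c(-1, 30)),
               "non-negative")
})

test_that("age adjustment removes exactly the linear age trend", {
  co <- make_cohort()
  age <- co$age
  # trait exactly linear in age: residuals vanish, all values = trait mean
  v1 <- stats::setNames(2 * age + 5, co$individual_id)
  adj1 <- adjust_for_age(v1, co)
  expect_equal(unname(adj1), rep(mean(v1), length(v1)))
  # trait orthogonal to age by construction: unchanged
  set.seed(1)
  e <- rnorm(length(age))
  e <- residuals(lm(e ~ age))        # force OLS slope zero
  v2 <- stats::setNames(50 + e, co$individual_id)
  adj2 <- adjust_for_age(v2, co)
  expect_equal(unname(adj2), unname(v2))
})

test_that("age adjustment matches the hand-computed OLS line", {
  co <- twin_cohort(c("a", "b", "c", "d"), c("p1", "p1", "p2", "p2"),
                    rep("MZ", 4), c(10, 20, 30, 40))
  v <- stats::setNames(c(1, 2, 4, 5), c("a", "b", "c", "d"))
  # slope = cov/var = 70/500 = 0.14; fitted = 3 + 0.14 (age - 25)
  # residuals (0.1, -0.3, 0.3, -0.1) plus mean 3.0
  expect_equal(unname(adjust_for_age(v, co)), c(3.1, 2.7, 3.3, 2.9))
})

test_that("age-adjusted residuals are orthogonal to age", {
  co <- make_cohort(10, 10)
  set.seed(7)
  v <- stats::setNames(30 + 0.3 * co$age + rnorm(40, 0, 4), co$individual_id)
  adj <- adjust_for_age(v, co)
  resid <- adj - mean(adj)
  agec <- co$age - mean(co$age)
  expect_lt(abs(sum(resid * agec)) / (sd(v) * sd(co$age) * 40), 1e-8)
})

test_that("age adjustment error modes", {
  co <- make_cohort(2, 2, age = rep(33, 8))
  v <- stats::setNames(rnorm(8), co$individual_id)
  expect_error(adjust_for_age(v, co), "unidentifiable")
  co2 <- make_cohort(2, 2)
  v2 <- stats::setNames(c(1, 2, rep(NA, 6)), co2$individual_id)
  expect_error(adjust_for_age(v2, co2), "fewer than 3")
})

test_that("double-entry pair correlation behaves as hand-computed", {
  co <- twin_cohort(c("a", "b", "c", "d"), c("p1", "p1", "p2", "p2"),
                    rep("MZ", 4), c(30, 30, 40, 40))
  # pairs (0,1) and (1,0): double-entered points give r = -1
  v <- stats::setNames(c(0, 1, 1, 0), c("a", "b", "c", "d"))
  expect_equal(pair_correlation(v, co, "MZ"), -1)
  # identical within pair, varying across pairs: r = 1
  v2 <- stats::setNames(c(3, 3, 9, 9), c("a", "b", "c", "d"))
  expect_equal(pair_correlation(v2, co, "MZ"), 1)
})

test_that("pair correlation is invariant to within-pair labeling", {
  co <- make_cohort(6, 6)
  set.seed(11)
  v <- stats::setNames(rnorm(24), co$individual_id)
  r1 <- pair_correlation(v, co, "DZ")
  # swap members of every pair
  swapped <- co$individual_id[rep(seq(1, 23, 2), each = 2) + c(1, 0)]
  v2 <- stats::setNames(v[swapped], co$individual_id)
  expect_equal(pair_correlation(v2, co, "DZ"), r1)
  # missing member drops the whole pair
  v3 <- v
  v3[co$individual_id[co$zygosity == "DZ"][1]] <- NA
  expect_false(identical(pair_correlation(v3, co, "DZ"), r1))
  expect_error(pair_correlation(stats::setNames(rep(1, 24), co$individual_id),
                                co, "MZ"),
               "zero variance")
})

test_that("Falconer decomposition follows the printed closed form", {
  fc <- falconer_decompose(0.8, 0.5)
  expect_equal(fc[, c("h2", "c2", "e2")],
               data.frame(h2 = 0.6, c2 = 0.2, e2 = 0.2))
  # equal twin correlations force h2 = 0
  fc2 <- falconer_decompose(0.4, 0.4)
  expect_equal(fc2$h2, 0)
  expect_equal(fc2$c2, 0.4)
  expect_equal(fc2$e2, 0.6)
  # raw estimates may be negative; clamping truncates and renormalizes
  fc3 <- falconer_decompose(0.2, 0.4)
  expect_equal(c(fc3$h2, fc3$c2, fc3$e2), c(-0.4, 0.6, 0.8))
  fc3c <- falconer_decompose(0.2, 0.4, clamp = TRUE)
  expect_equal(fc3c$h2, 0)
  expect_true(fc3c$clamped)
  expect_equal(fc3c$h2 + fc3c$c2 + fc3c$e2, 1)
  expect_equal(fc3c$c2 / fc3c$e2, 0.6 / 0.8)
  expect_error(falconer_decompose(NA, 0.2), "non-finite")
  expect_error(falconer_decompose(1.2, 0.2), "\\[-1, 1\\]")
})

test_that("h2 + c2 + e2 = V_p to machine precision", {
  set.seed(3)
  r_mz <- runif(200, -1, 1)
  r_dz <- runif(200, -1, 1)
  vp <- runif(200, 0.25, 4)
  fc <- falconer_decompose(r_mz, r_dz, V_p = vp)
  expect_lt(max(abs(fc$h2 + fc$c2 + fc$e2 - vp)), 1e-12)
})

test_that("variance components are invariant under affine trait rescaling", {
  p <- test_panel(2)
  truth <- plant_effects(p, c(0.1, 0), c0 = 0.3, noise_sd = 0, seed = 4)
  d <- simulate_cohort(truth, 30, 30, seed = 5)
  comp <- estimate_components(d)
  d2 <- d
  d2$csf <- 0.37 * d$csf + 12          # a > 0 affine rescaling
  d2$replicate <- 0.37 * d$replicate + 12
  comp2 <- estimate_components(d2)
  expect_equal(comp2[, c("r_mz", "r_dz", "h2", "c2", "e2")],
               comp[, c("r_mz", "r_dz", "h2", "c2", "e2")],
               tolerance = 1e-10)
})

test_that("trait quality filter applies the replicate and mean rules", {
  stats <- data.frame(
    subpopulation = c("a", "b", "c", "d", "e", "f"),
    mean_value = c(50, 50, 0.5, 1, 99, 50),
    replicate_correlation = c(0.31, 0.30, 0.9, 0.5, 0.5, NA))
  keep <- qc_filter_traits(stats)
  expect_identical(keep, c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  # traits lacking a replicate pass only when the filter is relaxed
  keep2 <- qc_filter_traits(stats, require_replicate = FALSE)
  expect_identical(keep2, c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
})

test_that("dataset filter needs at least 18 high-quality traits", {
  expect_true(qc_filter_dataset(18))
  expect_false(qc_filter_dataset(17))
  expect_false(qc_filter_dataset(0))
})
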