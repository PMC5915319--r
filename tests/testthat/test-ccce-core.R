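test_that("permutation p-value hits its lower bound on a noiseless signal", {
  p <- test_panel(4)
  X <- build_design_matrix(enumerate_subpopulations(p), p)
  y <- as.numeric(0.3 + 0.2 * X[, 1] - 0.1 * X[, 3])   # exactly realizable
  pv <- permutation_pvalue(X, y, K = 3, n_perm = 99, rng_seed = 5)
  expect_equal(pv$p_value, 1 / 100)
  expect_length(pv$perm_errors, 99)
  expect_true(all(pv$perm_errors > pv$observed$prediction_error))
})

test_that("permutation p-value of a constant response is 1", {
  p <- test_panel(4)
  X <- build_design_matrix(enumerate_subpopulations(p), p)
  pv <- permutation_pvalue(X, rep(0.4, 16), K = 3, n_perm = 49, rng_seed = 2)
  expect_equal(pv$p_value, 1)
})

test_that("p-values stay inside [1/(n_perm+1), 1]", {
  p <- test_panel(4)
  X <- build_design_matrix(enumerate_subpopulations(p), p)
  for (s in 1:5) {
    set.seed(s)
    y <- rnorm(16, 0.3, 0.1)
    pv <- permutation_pvalue(X, y, K = 3, n_perm = 19, rng_seed = s)
    expect_gte(pv$p_value, 1 / 20)
    expect_lte(pv$p_value, 1)
  }
})

test_that("permuting panel markers permutes coefficients, nothing else", {
  p <- test_panel(5)
  X <- build_design_matrix(enumerate_subpopulations(p), p)
  set.seed(31)
  y <- 0.3 + 0.12 * X[, 2] + rnorm(32, 0, 0.05)
  perm <- c(4, 1, 5, 3, 2)
  p2 <- ccce_panel("test", paste0("M", perm))
  X2 <- X[, perm]
  colnames(X2) <- p2$markers
  pv1 <- permutation_pvalue(X, y, K = 6, n_perm = 29, rng_seed = 8)
  pv2 <- permutation_pvalue(X2, y, K = 6, n_perm = 29, rng_seed = 8)
  expect_equal(pv2$observed$coefficients,
               pv1$observed$coefficients[perm], tolerance = 1e-8)
  expect_equal(pv2$observed$prediction_error, pv1$observed$prediction_error)
  expect_equal(pv2$p_value, pv1$p_value)
  expect_equal(pv2$perm_errors, pv1$perm_errors)
})

test_that("permutation replicates parallelize without changing results", {
  p <- test_panel(4)
  X <- build_design_matrix(enumerate_subpopulations(p), p)
  set.seed(32)
  y <- rnorm(16, 0.3, 0.1)
  seq_run <- permutation_pvalue(X, y, K = 3, n_perm = 19, rng_seed = 3,
                                cores = 1)
  par_run <- permutation_pvalue(X, y, K = 3, n_perm = 19, rng_seed = 3,
                                cores = 2)
  expect_identical(par_run$perm_errors, seq_run$perm_errors)
  expect_identical(par_run$p_value, seq_run$p_value)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_identical(fdr_adjust(numeric(0)), numeric(0))
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
  # q >= p, q in (0, 1], and thresholding q reproduces textbook BH step-up
  set.seed(33)
  pv <- runif(40)^2
  q <- fdr_adjust(pv)
  expect_true(all(q >= pv & q <= 1))
  m <- length(pv)
  o <- order(pv)
  alpha <- 0.1
  passed <- which(pv[o] <= alpha * seq_len(m) / m)
  bh_reject <- if (length(passed)) o[seq_len(max(passed))] else integer(0)
  expect_setequal(which(q <= alpha), bh_reject)
})

test_that("leading subfunction extraction handles sign, ties and zero fits", {
  p <- ccce_panel("t", c("A", "B", "C"))
  l <- leading_subfunction(stats::setNames(c(0.5, -0.9, 0.1), c("A", "B", "C")), p)
  expect_identical(l$marker, "B")
  expect_identical(l$sign, "negative")
  expect_equal(l$coefficient, -0.9)
  expect_false(l$tie)
  lz <- leading_subfunction(stats::setNames(rep(0, 3), c("A", "B", "C")))
  expect_true(lz$none)
  expect_length(lz$marker, 0)
  lt <- leading_subfunction(stats::setNames(c(0.4, -0.4), c("A", "B")))
  expect_true(lt$tie)
  expect_identical(lt$marker, c("A", "B"))
  expect_identical(lt$sign, c("positive", "negative"))
})

test_that("dataset pipeline finds a planted subfunction effect", {
  p <- test_panel(5)
  truth <- plant_effects(p, c(0, 0, 0.2, 0, 0), c0 = 0.3, noise_sd = 0.05,
                         seed = 41)
  d <- simulate_cohort(truth, 200, 200, seed = 42)
  res <- run_ccce_dataset(d, n_perm = 99, rng_seed = 43)
  expect_s3_class(res, "ccce_result")
  expect_equal(res$n_traits, 32)
  expect_lte(res$p_value, 0.05)
  expect_identical(res$leading$marker, "M3")
  expect_identical(res$leading$sign, "positive")
  expect_equal(nrow(res$components), 32)
  # same dataset + same seed: identical result
  res2 <- run_ccce_dataset(d, n_perm = 99, rng_seed = 43)
  expect_identical(res2[setdiff(names(res2), "config")],
                   res[setdiff(names(res), "config")])
})

test_that("precomputed c2 tables bypass the twin variance stage", {
  p <- test_panel(5)
  sig <- enumerate_subpopulations(p)
  set.seed(44)
  c2 <- stats::setNames(0.3 + 0.2 * sig[, 2] + rnorm(32, 0, 0.02),
                        rownames(sig))
  res <- run_ccce_dataset(c2 = c2, panel = p, n_perm = 99, rng_seed = 45)
  expect_null(res$components)
  expect_identical(res$leading$marker, "M2")
  expect_lte(res$p_value, 0.05)
})

test_that("stage errors are tagged and QC failures are explicit", {
  p <- test_panel(5)
  d <- simulate_cohort(plant_effects(p, rep(0, 5), 0.3, 0, seed = 1),
                       20, 20, seed = 2)
  expect_error(run_ccce_dataset(d, min_traits = 40, n_perm = 9),
               "fails QC")
  expect_error(run_ccce_dataset(c2 = stats::setNames(rep(0.3, 2), c("a", "b")),
                                panel = p, n_perm = 9),
               "design stage")
  expect_error(run_ccce_dataset(n_perm = 9), "supply")
})

test_that("extra pure-noise markers do not make the test more significant", {
  # trend over simulations, not per run: mean p with 2 appended noise
  # markers must not fall below mean p of the informative design
  p4 <- test_panel(4)
  X <- build_design_matrix(enumerate_subpopulations(p4), p4)
  p_small <- p_big <- numeric(40)
  for (s in 1:40) {
    set.seed(100 + s)
    y <- as.numeric(0.3 + 0.06 * X[, 1] + rnorm(16, 0, 0.1))
    Xn <- cbind(X, matrix(sample(c(-1, 1), 32, TRUE), 16, 2,
                          dimnames = list(NULL, c("N1", "N2"))))
    p_small[s] <- permutation_pvalue(X, y, K = 3, n_perm = 39,
                                     rng_seed = s)$p_value
    p_big[s] <- permutation_pvalue(Xn, y, K = 3, n_perm = 39,
                                   rng_seed = s)$p_value
  }
  expect_gte(mean(p_big), mean(p_small) - 0.02)
})

test_that("cross-dataset analysis ranks a planted effect above a null", {
  p <- test_panel(5)
  truth <- plant_effects(p, c(0.2, 0, 0, 0, 0), c0 = 0.3, noise_sd = 0.05,
                         seed = 51)
  d_sig <- simulate_cohort(truth, 150, 150, seed = 52)
  d_sig$panel$cell_type <- "planted"
  d_null <- simulate_null(p, 150, 150, seed = 53)
  d_null$panel$cell_type <- "null"
  an <- run_ccce(list(d_sig, d_null), rng_seed = 7, n_perm = 49)
  expect_identical(nrow(an$summary), 2L)
  expect_identical(an$summary$cell_type[1], "planted")
  expect_true(all(an$summary$fdr >= an$summary$p_value))
  expect_identical(an$results[[1]]$fdr, an$summary$fdr[1])
})
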