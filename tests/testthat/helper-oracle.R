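# Independent elastic-net oracles used to cross-check the package solver.
#
# enet_oracle solves the same objective,
#   (1/2n) ||y - b0 - X b||^2 + penalty * (mixing ||b||_1 +
#                                          (1 - mixing)/2 ||b||_2^2),
# by a deliberately different route: the intercept is eliminated analytically
# (centering X and y), and coordinate descent runs on the reduced problem
# with vectorized residual updates. Written independently of src/enet.cpp.
enet_oracle <- function(X, y, penalty, mixing, tol = 1e-13, max_iter = 200000L) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  yc <- y - ym
  n <- nrow(X)
  k <- ncol(X)
  xsq <- colMeans(Xc^2)
  l1 <- penalty * mixing
  l2 <- penalty * (1 - mixing)
  b <- rep(0, k)
  r <- yc
  for (it in seq_len(max_iter)) {
    maxd <- 0
    for (j in seq_len(k)) {
      z <- mean(Xc[, j] * r) + xsq[j] * b[j]
      denom <- xsq[j] + l2
      bn <- if (denom <= 0) 0 else sign(z) * max(abs(z) - l1, 0) / denom
      d <- bn - b[j]
      if (d != 0) {
        r <- r - d * Xc[, j]
        b[j] <- bn
        maxd <- max(maxd, abs(d))
      }
    }
    if (maxd < tol) break
  }
  list(coefficients = stats::setNames(b, colnames(X)),
       intercept = ym - sum(xm * b))
}

# Closed form for a full-factorial +1/-1 design (X'X = n I, zero column
# means): b_j = S((1/n) sum_i x_ij y_i, penalty*mixing) /
#              (1 + penalty*(1 - mixing)), intercept = mean(y).
enet_factorial_closed_form <- function(X, y, penalty, mixing) {
  z <- as.numeric(crossprod(X, y - mean(y))) / nrow(X)
  b <- sign(z) * pmax(abs(z) - penalty * mixing, 0) / (1 + penalty * (1 - mixing))
  list(coefficients = stats::setNames(b, colnames(X)), intercept = mean(y))
}

# Relative discrepancy between two coefficient sets, guarded for near-zero
# references.
rel_coef_diff <- function(a, b) {
  max(abs(a - b)) / max(max(abs(b)), 1e-8)
}

test_panel <- function(k, cell_type = "test") {
  ccce_panel(cell_type, paste0("M", seq_len(k)))
}
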