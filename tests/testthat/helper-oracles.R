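# independent oracle: posterior mean/SD of beta for the Gaussian
# random-intercept model by 2-D grid integration over the two SDs
# (flat prior on fixed effects, half-t(3, 0, scale) on both SDs)
grid_beta_oracle <- function(y, X, Z, A, scale, ngrid = 40) {
  smax <- 3 * sd(y)
  sb_grid <- seq(smax / 200, smax, length.out = ngrid)
  se_grid <- seq(smax / 200, smax, length.out = ngrid)
  n <- length(y)
  lw <- matrix(NA_real_, ngrid, ngrid)
  bm <- matrix(NA_real_, ngrid, ngrid)
  bv <- matrix(NA_real_, ngrid, ngrid)
  lht <- function(s) -2 * log1p((s / scale)^2 / 3)
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid)) {
    Sigma <- se_grid[j]^2 * diag(n) + sb_grid[i]^2 * Z %*% A %*% t(Z)
    Si <- solve(Sigma)
    XtSiX <- t(X) %*% Si %*% X
    bhat <- solve(XtSiX, t(X) %*% Si %*% y)
    quad <- drop(t(y) %*% Si %*% y - t(bhat) %*% XtSiX %*% bhat)
    lw[i, j] <- -0.5 * determinant(Sigma)$modulus -
      0.5 * determinant(XtSiX)$modulus - 0.5 * quad +
      lht(sb_grid[i]) + lht(se_grid[j])
    bm[i, j] <- bhat[2]
    bv[i, j] <- solve(XtSiX)[2, 2]
  }
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  mean_beta <- sum(w * bm)
  var_beta <- sum(w * (bv + bm^2)) - mean_beta^2
  list(mean = mean_beta, sd = sqrt(var_beta))
}
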