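#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall rank correlation between two aligned vectors.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Tau-b in `[-1, 1]`; `NA` with a warning when either vector is
#'   entirely tied (tau undefined).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 paired values")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("tau undefined for an all-tied vector")
    return(NA_real_)
  }
  unname(cor(x, y, method = "kendall"))
}

#' Monte-Carlo propagated Kendall tau with probability of direction
#'
#' Concordance between temperature-induced changes in two quantities whose
#' per-condition values are estimates with standard errors. Each iteration
#' draws every condition value independently from
#' `Normal(mean, se^2)` and computes tau-b; the point estimate pools
#' iterations on the Fisher-z scale (tau clipped to `1 - 1e-6` in absolute
#' value before `atanh`) and back-transforms. The probability of direction
#' is the fraction of iterations whose tau shares the sign of the point
#' estimate (exact-zero iterations match neither sign).
#'
#' @param means_x,ses_x,means_y,ses_y Aligned condition vectors (length
#'   >= 2, SEs >= 0).
#' @param n_mc Monte-Carlo iterations (default 10000).
#' @param seed Optional integer seed.
#' @return An object of class `"concordance_result"`: `tau`, `p_d`,
#'   `n_conditions`, `n_mc`.
#' @export
mc_concordance <- function(means_x, ses_x, means_y, ses_y, n_mc = 10000,
                           seed = NULL) {
  k <- length(means_x)
  if (length(ses_x) != k || length(means_y) != k || length(ses_y) != k)
    stop("all inputs must have the same length")
  if (k < 2) stop("need at least 2 conditions")
  if (any(c(ses_x, ses_y) < 0)) stop("SEs must be nonnegative")

  if (all(ses_x == 0) && all(ses_y == 0)) {
    # degenerate sampling: every iteration reproduces the point tau
    tau <- kendall_tau(means_x, means_y)
    return(structure(list(tau = tau,
                          p_d = if (is.na(tau) || tau == 0) 0.5 else 1,
                          n_conditions = k, n_mc = n_mc),
                     class = "concordance_result"))
  }

  run <- function() {
    taus <- numeric(n_mc)
    for (i in seq_len(n_mc)) {
      sx <- means_x + rnorm(k, 0, ses_x)
      sy <- means_y + rnorm(k, 0, ses_y)
      taus[i] <- cor(sx, sy, method = "kendall")
    }
    taus
  }
  taus <- if (is.null(seed)) run() else with_seed(seed, run())
  taus <- taus[!is.na(taus)]
  if (!length(taus)) stop("all Monte-Carlo iterations produced undefined tau")
  clip <- 1 - 1e-6
  point <- tanh(mean(atanh(pmin(pmax(taus, -clip), clip))))
  p_d <- if (point == 0) 0.5 else mean(sign(taus) == sign(point))
  structure(list(tau = point, p_d = max(p_d, 0.5), n_conditions = k,
                 n_mc = n_mc), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo Kendall tau = %+.3f, p_d = %.3f (n = %d conditions, %d draws)\n",
              x$tau, x$p_d, x$n_conditions, x$n_mc))
  invisible(x)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `r`, `r_squared`, `p` (two-sided, t distribution
#'   with n - 2 df) and `n`. Zero variance in either vector yields `NA`
#'   with a warning.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (var(x) == 0 || var(y) == 0) {
    warning("correlation undefined under zero variance")
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}
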