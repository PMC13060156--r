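#' Exclude low-count egg-lay replicates
#'
#' Replicates with fewer than `min_total` embryos carry little information
#' about hatch probability and are excluded before model fitting.
#'
#' @param records Cross-record data.frame with column `eggs_total`.
#' @param min_total Minimum embryo count to retain (inclusive; default 10).
#' @return The retained rows, in their original order.
#' @export
filter_min_eggs <- function(records, min_total = 10) {
  stopifnot(is.data.frame(records), "eggs_total" %in% names(records))
  out <- records[records$eggs_total >= min_total, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gauss-Hermite nodes/weights rescaled for a N(0, sigma^2) mixing density:
# integral f(u) dnorm(u; 0, sigma) du ~= sum_k w_k f(sqrt(2) sigma x_k) / sqrt(pi)
gh_rule <- function(order) {
  gh <- pracma::gaussHermite(order)
  list(x = gh$x, w = gh$w / sqrt(pi))
}

#' Marginal log-likelihood of the zero-inflated binomial mixed model
#'
#' Each replicate contributes
#' `log( pi * 1\{y = 0\} + (1 - pi) * Integral Binom(y; n, plogis(eta + u))
#' dNorm(u; 0, sigma^2) )`, the random replicate effect integrated out by
#' Gauss-Hermite quadrature.
#'
#' @param params A list with `eta` (named logit means keyed
#'   `strain|temp|cross`), `sigma` (OLRE SD, >= 0) and `pi`
#'   (zero-inflation probability).
#' @param records Data.frame with `strain`, `temperature_c`, `cross_type`,
#'   `eggs_total`, `eggs_hatched`.
#' @param quad_order Number of quadrature nodes (>= 5).
#' @return The scalar log-likelihood.
#' @export
zib_marginal_loglik <- function(params, records, quad_order = 25) {
  if (quad_order < 5) stop("quad_order must be >= 5")
  keys <- cell_key(records$strain, records$temperature_c, records$cross_type)
  unknown <- setdiff(keys, names(params$eta))
  if (length(unknown))
    stop("record(s) in cell(s) with no logit mean: ",
         paste(unique(unknown), collapse = "; "))
  eta <- unname(params$eta[keys])
  y <- records$eggs_hatched
  n <- records$eggs_total
  sigma <- params$sigma
  pi0 <- params$pi %||% 0

  if (sigma > 0) {
    gh <- gh_rule(quad_order)
    K <- length(gh$x)
    E <- outer(eta, sqrt(2) * sigma * gh$x, `+`)
    P <- matrix(dbinom(rep(y, K), rep(n, K), plogis(as.vector(E))),
                nrow = length(y))
    lik <- as.vector(P %*% gh$w)
  } else {
    lik <- dbinom(y, n, plogis(eta))
  }
  mix <- pi0 * (y == 0) + (1 - pi0) * lik
  ll <- sum(log(pmax(mix, 1e-300)))
  if (!is.finite(ll)) {
    bad <- which(!is.finite(log(pmax(mix, 1e-300))))
    stop("non-finite log-likelihood at record index ", bad[1])
  }
  ll
}

# Moore-Penrose pseudo-inverse via SVD (used when observed information is
# numerically singular).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit the zero-inflated binomial mixed model
#'
#' Maximizes [zib_marginal_loglik()] over a saturated cell-means
#' parameterization (one logit per strain x temperature x cross cell), the
#' log OLRE SD, and the logit zero-inflation probability. The covariance of
#' the estimates is the inverse of the numerically differentiated observed
#' information. If the zero-inflated fit does not converge (optimizer
#' failure or singular information, e.g. when no replicate is a zero and pi
#' is unidentifiable), the model is refitted without zero-inflation and
#' `zero_inflated` is set to `FALSE`.
#'
#' Cells in which every egg hatched (or none did) have no finite logit
#' optimum; cell logits are therefore box-constrained to `[-cap, cap]` and
#' cells ending on the boundary are flagged in `capped_cells`.
#'
#' @param records Filtered cross records (see [filter_min_eggs()]).
#' @param design Optional `"ci_design"`; if given, every design cell must
#'   have at least one record.
#' @param quad_order Gauss-Hermite order (default 40, which keeps the
#'   marginal log-likelihood within 1e-6 of a brute-force integral across
#'   the parameter ranges the model visits).
#' @param zero_inflated Attempt the zero-inflated fit first (default TRUE).
#' @param n_starts Number of optimizer starts; the best likelihood wins.
#' @param cap Logit bound for degenerate cells (default 8).
#' @return An object of class `"zib_fit"`.
#' @export
fit_zib_glmm <- function(records, design = NULL, quad_order = 40,
                         zero_inflated = TRUE, n_starts = 3, cap = 8) {
  stopifnot(nrow(records) > 0)
  keys <- cell_key(records$strain, records$temperature_c, records$cross_type)
  cells <- sort(unique(keys))
  if (!is.null(design)) {
    want <- expand_cells(design)
    want_keys <- cell_key(want$strain, want$temperature, want$cross_type)
    empty <- setdiff(want_keys, cells)
    if (length(empty))
      stop("design cell(s) with zero records: ",
           paste(empty, collapse = "; "))
  }

  y <- records$eggs_hatched
  n <- records$eggs_total
  cell_idx <- match(keys, cells)
  gh <- gh_rule(quad_order)
  K <- length(gh$x)
  nc <- length(cells)
  any_zero <- any(y == 0)

  nll <- function(theta, zi) {
    eta <- theta[seq_len(nc)][cell_idx]
    sigma <- exp(theta[nc + 1])
    E <- outer(eta, sqrt(2) * sigma * gh$x, `+`)
    P <- matrix(dbinom(rep(y, K), rep(n, K), plogis(as.vector(E))),
                nrow = length(y))
    lik <- as.vector(P %*% gh$w)
    if (zi) {
      pi0 <- plogis(theta[nc + 2])
      lik <- pi0 * (y == 0) + (1 - pi0) * lik
    }
    -sum(log(pmax(lik, 1e-300)))
  }

  emp_logit <- qlogis((tapply(y, cell_idx, sum) + 0.5) /
                      (tapply(n, cell_idx, sum) + 1))
  emp_logit <- pmin(pmax(emp_logit, -cap), cap)

  run_fit <- function(zi) {
    npar <- nc + 1 + zi
    lower <- c(rep(-cap, nc), log(1e-3), if (zi) -12)
    upper <- c(rep(cap, nc), log(10), if (zi) 6)
    starts <- lapply(seq_len(n_starts), function(s) {
      jit <- if (s == 1) 0 else rnorm(nc, 0, 0.3)
      c(pmin(pmax(emp_logit + jit, -cap), cap),
        log(c(0.5, 0.2, 1.0)[(s - 1) %% 3 + 1]),
        if (zi) qlogis(c(0.05, 0.02, 0.10)[(s - 1) %% 3 + 1]))
    })
    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        optim(st, nll, zi = zi, method = "L-BFGS-B",
              lower = lower, upper = upper,
              control = list(maxit = 500, factr = 1e8)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value))
        best <- opt
    }
    best
  }

  make_fit <- function(opt, zi) {
    theta <- opt$par
    H <- tryCatch(optimHess(theta, nll, zi = zi), error = function(e) NULL)
    singular <- FALSE
    V <- NULL
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0)) {
        V <- pinv(H)
        singular <- TRUE
      }
      V <- (V + t(V)) / 2
    } else {
      V <- matrix(NA_real_, length(theta), length(theta))
      singular <- TRUE
    }
    pnames <- c(cells, "log_sigma", if (zi) "logit_pi")
    dimnames(V) <- list(pnames, pnames)
    capped <- cells[abs(theta[seq_len(nc)]) >= cap - 1e-6]
    structure(list(
      cell_coef = setNames(unname(theta[seq_len(nc)]), cells),
      olre_sigma = unname(exp(theta[nc + 1])),
      zi_prob = if (zi) unname(plogis(theta[nc + 2])) else 0,
      vcov = V, param_names = pnames,
      loglik = -opt$value, n_obs = length(y),
      converged = opt$convergence == 0 && !singular,
      zero_inflated = zi, singular_info = singular,
      capped_cells = capped, quad_order = quad_order),
      class = "zib_fit")
  }

  if (zero_inflated && any_zero) {
    opt <- run_fit(TRUE)
    if (!is.null(opt)) {
      fit <- make_fit(opt, TRUE)
      if (fit$converged) return(fit)
    }
  }
  # fallback (or requested) non-zero-inflated model
  opt <- run_fit(FALSE)
  if (is.null(opt)) stop("optimization failed for both model variants")
  fit <- make_fit(opt, FALSE)
  if (fit$singular_info)
    warning("observed information singular; pseudo-inverse used for vcov")
  fit
}

#' @export
print.zib_fit <- function(x, ...) {
  cat(sprintf(
    "Zero-inflated binomial mixed model (%s)\n  cells: %d  n: %d  logLik: %.2f\n  OLRE sigma: %.3f  zero-inflation pi: %.4f  converged: %s\n",
    if (x$zero_inflated) "zero-inflation on" else "fallback, no zero-inflation",
    length(x$cell_coef), x$n_obs, x$loglik, x$olre_sigma, x$zi_prob,
    x$converged))
  if (length(x$capped_cells))
    cat("  boundary (capped) cells:", paste(x$capped_cells, collapse = ", "),
        "\n")
  invisible(x)
}

#' Estimated marginal means per cell
#'
#' Under the saturated cell-means parameterization the estimated marginal
#' mean of a strain x temperature x cross cell is its coefficient; the SE
#' is the Wald SE from the observed-information covariance.
#'
#' @param fit A `"zib_fit"`.
#' @return A data.frame (`strain`, `temperature_c`, `cross_type`, `cell`,
#'   `estimate`, `se`) on the logit scale.
#' @export
emm_cells <- function(fit) {
  stopifnot(inherits(fit, "zib_fit"))
  cells <- names(fit$cell_coef)
  parts <- do.call(rbind, strsplit(cells, "|", fixed = TRUE))
  data.frame(strain = parts[, 1], temperature_c = as.numeric(parts[, 2]),
             cross_type = parts[, 3], cell = cells,
             estimate = unname(fit$cell_coef),
             se = sqrt(diag(fit$vcov)[cells]),
             stringsAsFactors = FALSE, row.names = NULL)
}

contrast_from_L <- function(fit, L, label, scale = "log-odds") {
  cn <- names(fit$cell_coef)
  est <- sum(L * fit$cell_coef)
  V <- fit$vcov[cn, cn, drop = FALSE]
  se <- sqrt(drop(t(L) %*% V %*% L))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  base <- if (scale == "log2") 2 else exp(1)
  data.frame(label = label, log_estimate = est,
             ratio = base^est,
             ci_low = base^(est - 1.96 * se),
             ci_high = base^(est + 1.96 * se),
             se = se, p_raw = p, p_adj = NA_real_, scale = scale,
             stringsAsFactors = FALSE)
}

#' Odds-ratio contrast between two cells
#'
#' Back-transformed difference of cell logits: `OR = exp(eta_a - eta_b)`.
#' Used for CI strength (CI vs compatible cross, `OR_CI`) and rescue
#' efficiency (rescue vs compatible, `OR_R`). The Wald 95% interval and
#' two-sided normal p-value are computed on the log-odds scale;
#' `p_adj` is left `NA` until the caller adjusts its declared family with
#' [adjust_contrast_family()].
#'
#' @param fit A `"zib_fit"`.
#' @param cell_a,cell_b Cell keys (`strain|temp|cross`), numerator and
#'   denominator.
#' @param label Optional contrast label.
#' @return A one-row contrast data.frame.
#' @export
odds_ratio_contrast <- function(fit, cell_a, cell_b,
                                label = paste(cell_a, "/", cell_b)) {
  cn <- names(fit$cell_coef)
  if (!cell_a %in% cn) stop("unknown cell: ", cell_a)
  if (!cell_b %in% cn) stop("unknown cell: ", cell_b)
  L <- setNames(numeric(length(cn)), cn)
  L[cell_a] <- L[cell_a] + 1
  L[cell_b] <- L[cell_b] - 1
  out <- contrast_from_L(fit, L, label)
  if (cell_a == cell_b) out$p_raw <- 1  # identity contrast
  out
}

#' Ratio of odds ratios across two temperatures
#'
#' `OR_CI,T = OR_CI(cool) / OR_CI(warm)`: the double-difference contrast
#' `(eta_ci,cool - eta_comp,cool) - (eta_ci,warm - eta_comp,warm)` on the
#' log-odds scale, back-transformed. Values below 1 indicate stronger CI at
#' the cooler temperature.
#'
#' @param fit A `"zib_fit"`.
#' @param pair_cool,pair_warm Length-2 character vectors
#'   `c(ci_cell, compatible_cell)` at the cool and warm temperature.
#' @param label Optional contrast label.
#' @return A one-row contrast data.frame.
#' @export
ratio_of_odds_ratios <- function(fit, pair_cool, pair_warm,
                                 label = "OR_CI,T") {
  cn <- names(fit$cell_coef)
  all_cells <- c(pair_cool, pair_warm)
  missing_c <- setdiff(all_cells, cn)
  if (length(missing_c))
    stop("unknown cell(s): ", paste(missing_c, collapse = ", "))
  L <- setNames(numeric(length(cn)), cn)
  L[pair_cool[1]] <- L[pair_cool[1]] + 1
  L[pair_cool[2]] <- L[pair_cool[2]] - 1
  L[pair_warm[1]] <- L[pair_warm[1]] - 1
  L[pair_warm[2]] <- L[pair_warm[2]] + 1
  contrast_from_L(fit, L, label)
}

#' Reconstruct a ratio of odds ratios from per-temperature odds ratios
#'
#' When the per-temperature CI odds ratios are already available (e.g. from
#' a published table), the temperature contrast is their quotient:
#' `OR_CI,T = OR_CI(cool) / OR_CI(warm)`.
#'
#' @param or_cool,or_warm Positive odds ratios at the cooler and warmer
#'   temperature.
#' @return The ratio of odds ratios.
#' @examples
#' or_ci_t(4.8e-3, 1.27)   # strong CI only at the cooler temperature
#' @export
or_ci_t <- function(or_cool, or_warm) {
  if (any(or_cool <= 0) || any(or_warm <= 0))
    stop("odds ratios must be positive")
  or_cool / or_warm
}

#' Apply FDR adjustment to a declared contrast family
#'
#' @param contrasts A data.frame of stacked contrast rows (one family).
#' @return The same data.frame with `p_adj` filled by [bh_fdr()].
#' @export
adjust_contrast_family <- function(contrasts) {
  contrasts$p_adj <- bh_fdr(contrasts$p_raw)
  contrasts
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; output is monotone, elementwise at least the raw
#' p-value, and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Partial eta-squared from a chi-square statistic
#'
#' Effect size for a model term: `chi^2 / (chi^2 + n)` where `n` is the
#' number of observations entering the model.
#'
#' @param chisq Nonnegative chi-square statistic.
#' @param n Positive observation count.
#' @return A value in `[0, 1)`.
#' @export
partial_eta_sq <- function(chisq, n) {
  if (any(chisq < 0)) stop("chisq must be nonnegative")
  if (any(n < 1)) stop("n must be >= 1")
  chisq / (chisq + n)
}

# Terms of the full factorial over the factors present among the cells.
factorial_terms <- function(factors) {
  k <- length(factors)
  terms <- list()
  for (ord in seq_len(k)) {
    cmb <- utils::combn(factors, ord, simplify = FALSE)
    terms <- c(terms, cmb)
  }
  terms
}

#' Type-II Wald chi-square tests for the hatch-model fixed effects
#'
#' Tests each factorial term (strain, temperature, cross type, and their
#' interactions) with a Wald chi-square that respects marginality: the
#' hypothesis space of a term is the span of its cell-level design columns
#' after projecting out every term that does not contain it. On balanced
#' complete designs this reproduces sequential (type-I) tests. Effect sizes
#' are partial eta-squared, `chi^2 / (chi^2 + n)`.
#'
#' @param fit A `"zib_fit"`.
#' @param factors Character vector of factor names to cross (defaults to
#'   the factors present in the cell keys: strain, temperature, cross).
#' @return A data.frame (`term`, `chisq`, `df`, `p`, `eta_sq_p`).
#' @export
typeII_wald_tests <- function(fit,
                              factors = c("strain", "temperature_c",
                                          "cross_type")) {
  stopifnot(inherits(fit, "zib_fit"))
  cells <- emm_cells(fit)
  for (f in factors) {
    cells[[f]] <- factor(cells[[f]])
    if (nlevels(cells[[f]]) < 2)
      stop("factor ", f, " has fewer than 2 levels among fitted cells")
  }
  eta <- cells$estimate
  cn <- cells$cell
  V <- fit$vcov[cn, cn, drop = FALSE]

  terms_list <- factorial_terms(factors)
  # sum-to-zero coding per factor, expanded to cell rows
  base_contr <- lapply(setNames(factors, factors), function(f) {
    C <- stats::contr.sum(nlevels(cells[[f]]))
    C[as.integer(cells[[f]]), , drop = FALSE]
  })
  # term design columns: row-wise products of the factors' contrast columns
  khatri <- function(A, B) {
    out <- matrix(0, nrow(A), ncol(A) * ncol(B))
    k <- 0
    for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
      k <- k + 1
      out[, k] <- A[, i] * B[, j]
    }
    out
  }
  mm_cols <- lapply(terms_list, function(tt)
    Reduce(khatri, base_contr[tt]))
  names(mm_cols) <- vapply(terms_list, paste, "", collapse = ":")

  out <- lapply(seq_along(terms_list), function(i) {
    tt <- terms_list[[i]]
    contains_t <- vapply(terms_list, function(u)
      all(tt %in% u) && length(u) > length(tt), TRUE)
    others <- do.call(cbind, c(list(matrix(1, nrow(cells), 1)),
                               mm_cols[!contains_t &
                                       seq_along(terms_list) != i]))
    Xt <- mm_cols[[i]]
    R <- Xt - qr.fitted(qr(others), Xt)  # rank-deficiency-safe projection
    qrR <- qr(R)
    r <- qrR$rank
    if (r == 0)
      return(data.frame(term = names(mm_cols)[i], chisq = 0, df = 0L,
                        p = 1, eta_sq_p = 0))
    full_df <- ncol(Xt)
    if (r < full_df)
      warning("term ", names(mm_cols)[i],
              " rank-deficient on this design; df reduced to ", r)
    L <- t(qr.Q(qrR)[, seq_len(r), drop = FALSE])
    est <- L %*% eta
    W <- L %*% V %*% t(L)
    chisq <- drop(t(est) %*% solve(W, est))
    data.frame(term = names(mm_cols)[i], chisq = chisq, df = as.integer(r),
               p = pchisq(chisq, r, lower.tail = FALSE),
               eta_sq_p = partial_eta_sq(chisq, fit$n_obs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
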