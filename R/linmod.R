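#' Factorial OLS on log2-transformed responses
#'
#' Fits a saturated cell-means linear model (one mean per factor-level
#' combination observed in the data) by least squares. Used for
#' log2-transformed Wolbachia/Wovirus densities and cifB transcript
#' abundances, with strain (or variant) and temperature as factors.
#'
#' @param table A data.frame holding the response and factor columns.
#' @param response Name of the (already log2-transformed) response column.
#' @param factors Character vector of factor column names.
#' @param allow_incomplete Permit missing factor-level combinations
#'   (default FALSE: an empty cell is an error naming the cell).
#' @return An object of class `"ols_fit"` with cell means, residual
#'   variance, residual df, and the coefficient covariance.
#' @export
fit_factorial_ols <- function(table, response, factors,
                              allow_incomplete = FALSE) {
  stopifnot(is.data.frame(table), response %in% names(table),
            all(factors %in% names(table)))
  y <- table[[response]]
  if (any(!is.finite(y))) stop("response contains non-finite values")
  fl <- lapply(setNames(factors, factors), function(f) factor(table[[f]]))
  cell <- interaction(fl, sep = "|", drop = FALSE)
  if (any(tabulate(cell, nbins = nlevels(cell)) == 0)) {
    empty <- levels(cell)[tabulate(cell, nbins = nlevels(cell)) == 0]
    if (!allow_incomplete)
      stop("empty factor cell(s): ", paste(empty, collapse = ", "))
    cell <- droplevels(cell)
  }
  # saturated cell-means least squares in closed form
  ncell <- nlevels(cell)
  df_resid <- length(y) - ncell
  if (df_resid < 1) stop("zero residual degrees of freedom")
  counts <- tabulate(cell, nbins = ncell)
  coefs <- setNames(as.numeric(tapply(y, cell, mean)), levels(cell))
  rv <- sum((y - coefs[as.integer(cell)])^2) / df_resid
  V <- diag(rv / counts, ncell)
  dimnames(V) <- list(levels(cell), levels(cell))
  structure(list(coef = coefs, residual_var = rv, df_resid = df_resid,
                 vcov = V, n_obs = length(y), factors = factors,
                 data = cbind(as.data.frame(fl), .y = y)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "Factorial OLS: %d cells (%s), n = %d, residual SD = %.3f on %d df\n",
    length(x$coef), paste(x$factors, collapse = " x "), x$n_obs,
    sqrt(x$residual_var), x$df_resid))
  invisible(x)
}

#' Type-II ANOVA F tests for a factorial OLS fit
#'
#' Computes type-II sums of squares by nested least-squares comparisons:
#' each term is tested against the model containing all terms that do not
#' contain it, with the error mean square taken from the full model. On
#' balanced designs this reproduces sequential (type-I) sums of squares.
#'
#' @param fit An `"ols_fit"`.
#' @return A data.frame (`term`, `ss`, `df`, `F`, `p`, `omega_sq_p`).
#' @export
typeII_anova_F <- function(fit) {
  stopifnot(inherits(fit, "ols_fit"))
  dat <- fit$data
  factors <- fit$factors
  terms_list <- factorial_terms(factors)
  term_names <- vapply(terms_list, paste, "", collapse = ":")
  ms_error <- fit$residual_var

  rss_of <- function(terms_subset) {
    if (length(terms_subset) == 0) {
      f <- .y ~ 1
    } else {
      f <- as.formula(paste(".y ~", paste(
        vapply(terms_subset, paste, "", collapse = ":"), collapse = " + ")))
    }
    m <- lm(f, data = dat)
    c(rss = sum(m$residuals^2), edf = m$rank)
  }

  out <- lapply(seq_along(terms_list), function(i) {
    tt <- terms_list[[i]]
    contains_t <- vapply(terms_list, function(u)
      all(tt %in% u) && length(u) > length(tt), TRUE)
    others <- terms_list[!contains_t & seq_along(terms_list) != i]
    m0 <- rss_of(others)
    m1 <- rss_of(c(others, terms_list[i]))
    ss <- m0["rss"] - m1["rss"]
    df <- m1["edf"] - m0["edf"]
    full_df <- prod(vapply(tt, function(f) nlevels(dat[[f]]) - 1L, 1L))
    if (df < full_df)
      warning("term ", term_names[i],
              " rank-deficient on this design; df reduced to ", df)
    if (df == 0)
      return(data.frame(term = term_names[i], ss = 0, df = 0L, F = NA_real_,
                        p = NA_real_, omega_sq_p = 0))
    Fv <- (ss / df) / ms_error
    data.frame(term = term_names[i], ss = unname(ss), df = as.integer(df),
               F = unname(Fv),
               p = unname(pf(Fv, df, fit$df_resid, lower.tail = FALSE)),
               omega_sq_p = partial_omega_sq(unname(ss), unname(df),
                                             ms_error, fit$n_obs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Partial omega-squared for a model term
#'
#' `omega^2_p = (ss - df * ms_error) / (ss + (n_obs - df) * ms_error)`.
#' Negative raw values (effects below the noise floor) are reported as 0;
#' the raw value is kept in the `"raw"` attribute.
#'
#' @param ss Term sum of squares.
#' @param df Term degrees of freedom.
#' @param ms_error Error mean square from the same fit.
#' @param n_obs Number of observations in the fit.
#' @return The (floored) partial omega-squared.
#' @export
partial_omega_sq <- function(ss, df, ms_error, n_obs) {
  if (ms_error < 0 || (ms_error == 0 && ss > 0)) {
    if (ms_error < 0) stop("ms_error must be nonnegative")
    return(structure(1, raw = 1))  # zero-noise limit
  }
  if (ms_error == 0) return(structure(0, raw = 0))
  raw <- (ss - df * ms_error) / (ss + (n_obs - df) * ms_error)
  structure(max(raw, 0), raw = raw)
}

#' Pairwise fold-change (risk-ratio) contrasts between cell means
#'
#' For a fixed level of one factor (e.g. a strain), compares estimated
#' marginal means across all level pairs of the other factor (e.g.
#' temperatures) on the log2 scale. The back-transformed ratio `2^Delta` is
#' the risk ratio RR; inference is t-based with the fit's residual df, and
#' the family of all pairs is FDR-adjusted together.
#'
#' @param fit An `"ols_fit"` over exactly two factors.
#' @param within Level of the conditioning factor.
#' @param across Name of the factor whose levels are compared.
#' @param conf_level Confidence level (default 0.95).
#' @return A data.frame of contrasts (`label`, `log_estimate`, `ratio`,
#'   `ci_low`, `ci_high`, `p_raw`, `p_adj`, `scale`).
#' @export
emm_pairwise_rr <- function(fit, within, across, conf_level = 0.95) {
  stopifnot(inherits(fit, "ols_fit"), length(fit$factors) == 2)
  cond <- setdiff(fit$factors, across)
  if (length(cond) != 1) stop("across must name one of the fit's factors")
  lv_within <- levels(fit$data[[cond]])
  if (!within %in% lv_within) stop("unknown level: ", within)
  idx_cond <- match(cond, fit$factors)
  keys <- names(fit$coef)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  here <- keys[parts[, idx_cond] == within]
  lv <- parts[parts[, idx_cond] == within, match(across, fit$factors)]
  if (length(here) < 2) stop("fewer than two levels of ", across,
                             " for ", within)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, fit$df_resid)
  rows <- list()
  for (i in seq_along(here)[-length(here)]) {
    for (j in seq((i + 1), length(here))) {
      a <- here[i]; b <- here[j]
      est <- fit$coef[[a]] - fit$coef[[b]]
      se <- sqrt(fit$vcov[a, a] + fit$vcov[b, b] - 2 * fit$vcov[a, b])
      tv <- if (se == 0 && est == 0) 0 else est / se  # exact-fit guard
      rows[[length(rows) + 1]] <- data.frame(
        label = paste0(within, ": ", lv[i], " / ", lv[j]),
        log_estimate = est, ratio = 2^est,
        ci_low = 2^(est - tcrit * se), ci_high = 2^(est + tcrit * se),
        se = se, p_raw = 2 * pt(-abs(tv), fit$df_resid),
        p_adj = NA_real_, scale = "log2", stringsAsFactors = FALSE)
    }
  }
  adjust_contrast_family(do.call(rbind, rows))
}
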