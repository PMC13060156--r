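#' Two-group permutation test on a mean difference
#'
#' Tests `mean(group_a) - mean(group_b)` against the permutation null
#' obtained by reshuffling group labels. The p-value is the pure proportion
#' of permuted absolute differences at least as large as the observed one;
#' when no permutation reaches it, the floor `1/(n_perm + 1)` is reported.
#'
#' @param group_a,group_b Numeric vectors (non-empty).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"perm_result"`: `observed_diff`, `n_perm`,
#'   `n_exceed`, `p`.
#' @export
permutation_diff_test <- function(group_a, group_b, n_perm = 10000,
                                  seed = NULL) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  obs <- mean(group_a) - mean(group_b)
  z <- c(group_a, group_b)
  na <- length(group_a)
  n <- length(z)
  if (var(z) == 0 || isTRUE(all.equal(max(z), min(z)))) {
    out <- list(observed_diff = 0, n_perm = n_perm, n_exceed = n_perm, p = 1)
    class(out) <- "perm_result"
    return(out)
  }
  run <- function() {
    tot <- sum(z)
    sa <- vapply(seq_len(n_perm), function(i) sum(z[sample.int(n, na)]), 1.0)
    diffs <- sa / na - (tot - sa) / (n - na)
    sum(abs(diffs) >= abs(obs) - 1e-12)
  }
  n_exceed <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- if (n_exceed == 0) 1 / (n_perm + 1) else n_exceed / n_perm
  structure(list(observed_diff = obs, n_perm = n_perm,
                 n_exceed = n_exceed, p = p), class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test: diff = %.4g, p = %.4g (%d of %d permutations)\n",
              x$observed_diff, x$p, x$n_exceed, x$n_perm))
  invisible(x)
}

# Gower-centered inner-product matrix of a Euclidean distance matrix
gower_center <- function(D) {
  A <- -0.5 * as.matrix(D)^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Sequential (type-I) PERMANOVA with Euclidean distance
#'
#' Partitions the Gower-centered inner-product matrix sequentially over the
#' given model terms (Anderson's method) and assesses each term's pseudo-F
#' against its permutation distribution under free permutation of
#' observations. For a univariate response under Euclidean distance, each
#' pseudo-F equals the classical sequential ANOVA F.
#'
#' @param values Numeric response vector, or a `dist` object.
#' @param factor_table Data.frame of factor columns (one row per
#'   observation).
#' @param term_order Character vector of model terms in fitting order,
#'   e.g. `c("system", "temperature", "system:temperature")`.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed.
#' @return A data.frame (`term`, `df`, `ss`, `r2`, `pseudo_f`, `p`) with a
#'   final `Residual` row (`p = NA`).
#' @export
permanova_seq <- function(values, factor_table, term_order, n_perm = 9999,
                          seed = NULL) {
  D <- if (inherits(values, "dist")) values else stats::dist(values)
  n <- attr(D, "Size")
  stopifnot(nrow(factor_table) == n)
  for (nm in names(factor_table))
    factor_table[[nm]] <- factor(factor_table[[nm]])
  G <- gower_center(D)
  ss_total <- sum(diag(G))

  # cumulative hat matrices
  Hs <- list()
  X <- matrix(1, n, 1)
  rank_prev <- 1
  H_prev <- matrix(1 / n, n, n)
  dfs <- integer(length(term_order))
  Ms <- vector("list", length(term_order))
  for (k in seq_along(term_order)) {
    f <- as.formula(paste("~", paste(term_order[seq_len(k)], collapse = "+")))
    Xk <- model.matrix(f, data = factor_table)
    qrk <- qr(Xk)
    Q <- qr.Q(qrk)[, seq_len(qrk$rank), drop = FALSE]
    Hk <- tcrossprod(Q)
    Ms[[k]] <- Hk - H_prev
    dfs[k] <- qrk$rank - rank_prev
    H_prev <- Hk
    rank_prev <- qrk$rank
  }
  M_res <- diag(n) - H_prev
  df_res <- n - rank_prev
  if (df_res < 1) stop("no residual degrees of freedom")

  ss_terms <- vapply(Ms, function(M) sum(M * G), 1.0)
  ss_res <- sum(M_res * G)
  if (ss_total <= 1e-12) {
    # constant response: nothing to partition
    out <- data.frame(term = c(term_order, "Residual"),
                      df = c(dfs, df_res),
                      ss = 0, r2 = c(rep(0, length(term_order)), 1),
                      pseudo_f = NA_real_,
                      p = c(rep(1, length(term_order)), NA_real_),
                      stringsAsFactors = FALSE)
    return(out)
  }
  ms_res <- ss_res / df_res
  F_obs <- ifelse(dfs > 0, (ss_terms / pmax(dfs, 1)) / ms_res, NA_real_)

  count_ge <- rep(0L, length(term_order))
  run <- function() {
    cnt <- rep(0L, length(term_order))
    for (b in seq_len(n_perm)) {
      pidx <- sample.int(n)
      Gp <- G[pidx, pidx]
      ssr <- sum(M_res * Gp) / df_res
      for (k in seq_along(Ms)) {
        if (dfs[k] == 0) next
        Fp <- (sum(Ms[[k]] * Gp) / dfs[k]) / ssr
        if (Fp >= F_obs[k] - 1e-12) cnt[k] <- cnt[k] + 1L
      }
    }
    cnt
  }
  if (n_perm > 0)
    count_ge <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- ifelse(dfs > 0, (count_ge + 1) / (n_perm + 1), 1)
  p[ss_terms <= 1e-12] <- 1

  out <- data.frame(term = c(term_order, "Residual"),
                    df = c(dfs, df_res),
                    ss = c(ss_terms, ss_res),
                    r2 = c(ss_terms, ss_res) / ss_total,
                    pseudo_f = c(F_obs, NA_real_),
                    p = c(p, NA_real_), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bootstrap percentile confidence interval for a mean
#'
#' Percentile interval of the resampled mean. Groups without variance get
#' the degenerate interval `(v, v)` flagged with attribute
#' `degenerate = TRUE`.
#'
#' @param values Numeric vector (>= 2 values for a non-degenerate interval).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Length-2 numeric vector `c(low, high)`.
#' @export
bootstrap_percentile_ci <- function(values, n_boot = 10000, level = 0.95,
                                    seed = NULL) {
  n <- length(values)
  if (n < 1) stop("empty input")
  if (n < 2 || var(values) == 0) {
    v <- values[1]
    return(structure(c(v, v), degenerate = TRUE))
  }
  run <- function() {
    resamp <- matrix(sample(values, n * n_boot, replace = TRUE), nrow = n)
    sort(colMeans(resamp))
  }
  stats_sorted <- if (is.null(seed)) run() else with_seed(seed, run())
  alpha <- (1 - level) / 2
  lo_i <- max(1L, floor((n_boot + 1) * alpha))
  hi_i <- min(n_boot, ceiling((n_boot + 1) * (1 - alpha)))
  structure(c(stats_sorted[lo_i], stats_sorted[hi_i]), degenerate = FALSE)
}

#' Pairwise development-time permutation tests
#'
#' Runs [permutation_diff_test()] for the two families the development-time
#' analysis declares: cytotype (symbiotic minus aposymbiotic, `delta_t`)
#' within each strain-temperature cell, and each temperature pair within
#' each strain-cytotype cell. Each family is FDR-adjusted separately.
#'
#' @param devtime Data.frame (`strain`, `cytotype`, `temperature_c`,
#'   `emergence_day`).
#' @param n_perm Permutations per test (default 10000).
#' @param seed Optional master seed; each test gets a child stream.
#' @return A list with data.frames `cytotype` and `temperature`.
#' @export
pairwise_devtime_tests <- function(devtime, n_perm = 10000, seed = NULL) {
  res_cyto <- list()
  counter <- 0L
  next_seed <- function() {
    counter <<- counter + 1L
    if (is.null(seed)) NULL else child_seed(seed, 10L + counter)
  }
  for (s in unique(devtime$strain)) {
    for (t in sort(unique(devtime$temperature_c[devtime$strain == s]))) {
      sub <- devtime[devtime$strain == s & devtime$temperature_c == t, ]
      a <- sub$emergence_day[sub$cytotype == "symbiotic"]
      b <- sub$emergence_day[sub$cytotype == "aposymbiotic"]
      if (!length(a) || !length(b)) next
      r <- permutation_diff_test(a, b, n_perm, seed = next_seed())
      res_cyto[[length(res_cyto) + 1]] <- data.frame(
        strain = s, temperature_c = t, delta_t = r$observed_diff,
        p_raw = r$p, stringsAsFactors = FALSE)
    }
  }
  res_temp <- list()
  for (s in unique(devtime$strain)) {
    for (cy in unique(devtime$cytotype)) {
      sub <- devtime[devtime$strain == s & devtime$cytotype == cy, ]
      temps <- sort(unique(sub$temperature_c))
      if (length(temps) < 2) next
      for (i in seq_along(temps)[-length(temps)]) {
        for (j in seq(i + 1, length(temps))) {
          a <- sub$emergence_day[sub$temperature_c == temps[i]]
          b <- sub$emergence_day[sub$temperature_c == temps[j]]
          r <- permutation_diff_test(a, b, n_perm, seed = next_seed())
          res_temp[[length(res_temp) + 1]] <- data.frame(
            strain = s, cytotype = cy, temp_a = temps[i], temp_b = temps[j],
            diff = r$observed_diff, p_raw = r$p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  cyto <- do.call(rbind, res_cyto)
  temp <- do.call(rbind, res_temp)
  if (!is.null(cyto)) cyto$p_adj <- bh_fdr(cyto$p_raw)
  if (!is.null(temp)) temp$p_adj <- bh_fdr(temp$p_raw)
  list(cytotype = cyto, temperature = temp)
}
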