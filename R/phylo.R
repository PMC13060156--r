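#' Parse and validate a relative chronogram
#'
#' Reads a newick tree, checks branch lengths and tip uniqueness, and
#' rescales all branch lengths so the root-to-tip height is exactly 1.
#' The tree must be ultrametric (equal root-to-tip paths) within 1e-6 of
#' the height; the offending tip is named otherwise.
#'
#' @param text A newick string, or a path to a file containing one.
#' @return An `ape::phylo` tree of class `c("chronogram", "phylo")` with
#'   unit height.
#' @export
parse_newick_chronogram <- function(text) {
  tr <- if (file.exists(text) && !grepl("\\(", text))
    ape::read.tree(text) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick input")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length))
    stop("every branch must carry a length")
  if (anyDuplicated(tr$tip.label))
    stop("tip labels must be unique: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  h <- max(depths)
  if (h <= 0) stop("tree has zero height")
  rel_err <- abs(depths - h) / h
  if (any(rel_err > 1e-6)) {
    # name the tip deviating most from the bulk of the root-to-tip depths
    bad <- tr$tip.label[which.max(abs(depths - median(depths)))]
    stop("tree is not ultrametric; offending tip: ", bad)
  }
  tr$edge.length <- tr$edge.length / h
  class(tr) <- c("chronogram", "phylo")
  tr
}

#' Phylogenetic covariance matrix from a chronogram
#'
#' `A[i, j]` is the shared branch length from the root to the most recent
#' common ancestor of tips i and j (the Brownian-motion covariance); the
#' diagonal equals the unit tree height.
#'
#' @param tree A `"chronogram"` (see [parse_newick_chronogram()]).
#' @return A symmetric positive-semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  A <- ape::vcv(tree)
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) stop("covariance matrix not positive semidefinite")
  A
}

# log density of a half-Student-t(df, 0, scale) prior at sigma > 0
log_half_t <- function(sigma, df = 3, scale = 1) {
  -((df + 1) / 2) * log1p((sigma / scale)^2 / df)
}

# Univariate stepping-out slice sampler (Neal 2003) for a log-density.
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50,
                          lower = -Inf, upper = Inf) {
  f0 <- logf(x0)
  logy <- f0 - rexp(1)
  u <- runif(1)
  L <- max(x0 - w * u, lower)
  R <- min(L + w, upper)
  k <- max_steps
  while (k > 0 && L > lower && logf(L) > logy) { L <- max(L - w, lower); k <- k - 1 }
  k <- max_steps
  while (k > 0 && R < upper && logf(R) > logy) { R <- min(R + w, upper); k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

run_phylo_chain <- function(y, X, Z, Ainv, n_iter, warmup, prior_scale,
                            thin = 1) {
  n <- length(y)
  q <- ncol(Z)
  W <- cbind(X, Z)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  p_fix <- ncol(X)
  sig_e <- sd(y) * 0.5 + 1e-3
  sig_p <- sd(y) * 0.5 + 1e-3
  theta <- rep(0, p_fix + q)
  keep <- floor((n_iter - warmup) / thin)
  out <- matrix(NA_real_, keep, 5,
                dimnames = list(NULL, c("alpha", "beta", "sigma_phylo",
                                        "sigma_resid", "r2")))
  kept <- 0L
  for (it in seq_len(n_iter)) {
    # location block: flat prior on fixed effects, N(0, sig_p^2 A) on b
    Q <- WtW / sig_e^2
    ridx <- p_fix + seq_len(q)
    Q[ridx, ridx] <- Q[ridx, ridx] + Ainv / sig_p^2
    ch <- chol(Q + diag(1e-10, nrow(Q)))
    m <- backsolve(ch, forwardsolve(t(ch), Wty / sig_e^2))
    theta <- m + backsolve(ch, rnorm(length(m)))
    b <- theta[ridx]
    resid <- y - W %*% theta
    ssr <- sum(resid^2)
    bAb <- drop(t(b) %*% Ainv %*% b)
    # residual SD: slice on log sigma
    lf_e <- function(ls) {
      s <- exp(ls)
      -n * ls - ssr / (2 * s^2) + log_half_t(s, scale = prior_scale) + ls
    }
    sig_e <- exp(slice_sample1(log(sig_e), lf_e, lower = log(1e-8),
                               upper = log(1e8)))
    # phylogenetic SD
    lf_p <- function(ls) {
      s <- exp(ls)
      -q * ls - bAb / (2 * s^2) + log_half_t(s, scale = prior_scale) + ls
    }
    sig_p <- exp(slice_sample1(log(sig_p), lf_p, lower = log(1e-8),
                               upper = log(1e8)))
    if (it > warmup && (it - warmup) %% thin == 0) {
      kept <- kept + 1L
      fitted <- drop(W %*% theta)
      vf <- var(fitted)
      out[kept, ] <- c(theta[1], theta[2], sig_p, sig_e,
                       vf / (vf + sig_e^2))
    }
  }
  out[seq_len(kept), , drop = FALSE]
}

#' Bayesian phylogenetic mixed regression
#'
#' Fits `y_i = alpha + beta * x_i + b_strain(i) + eps_i` with
#' `b ~ Normal(0, sigma_phylo^2 A)` and `eps ~ Normal(0, sigma_resid^2)`,
#' where `A` is the chronogram-derived covariance. Priors are flat on
#' `alpha` and `beta` and half-Student-t(3, 0, 2.5 sd(y)) on both SDs.
#' Sampling is Gibbs for the location block (fixed effects and strain
#' intercepts jointly) with stepping-out slice updates for the two SDs.
#'
#' @param y,x Numeric response and predictor (equal length).
#' @param strain_ids Strain label per observation; every label must appear
#'   in `rownames(A)`.
#' @param A Phylogenetic covariance (see [phylo_covariance()]); normalized
#'   to unit diagonal (correlation form) before fitting unless
#'   `scale_A = FALSE`.
#' @param chains Number of chains (default 4).
#' @param iters Iterations per chain including warmup (default 8000).
#' @param warmup Warmup iterations discarded per chain (default 2000).
#' @param seed Master seed; each chain uses a child stream.
#' @return A `"posterior_summary"` (see [posterior_summaries()]) with the
#'   chains attached as attribute `"draws"`.
#' @export
fit_phylo_mixed_model <- function(y, x, strain_ids, A, chains = 4,
                                  iters = 8000, warmup = 2000, seed = 1L,
                                  scale_A = TRUE) {
  stopifnot(length(y) == length(x), length(y) == length(strain_ids))
  if (length(unique(x)) < 3) stop("need at least 3 distinct predictor values")
  labs <- rownames(A)
  missing_s <- setdiff(unique(strain_ids), labs)
  if (length(missing_s))
    stop("strain(s) missing from covariance matrix: ",
         paste(missing_s, collapse = ", "))
  used <- labs[labs %in% unique(strain_ids)]
  A <- A[used, used, drop = FALSE]
  if (scale_A) A <- stats::cov2cor(A)
  ch <- tryCatch(chol(A + diag(1e-10, nrow(A))), error = function(e) NULL)
  if (is.null(ch)) stop("covariance matrix not positive semidefinite")
  Ainv <- chol2inv(ch)

  X <- cbind(1, x)
  Z <- outer(strain_ids, used, `==`) * 1
  prior_scale <- 2.5 * sd(y)
  if (!is.finite(prior_scale) || prior_scale <= 0) prior_scale <- 2.5

  draws <- lapply(seq_len(chains), function(cc)
    with_seed(child_seed(seed, 20L + cc),
              run_phylo_chain(y, X, Z, Ainv, iters, warmup, prior_scale)))
  posterior_summaries(draws)
}

# split-half R-hat (Gelman et al.) for one parameter across chains
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n2 <- floor(length(ch) / 2)
    halves <- c(halves, list(ch[seq_len(n2)], ch[n2 + seq_len(n2)]))
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 1.0)
  vars <- vapply(halves, var, 1.0)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize posterior draws of the phylogenetic regression
#'
#' @param draws A list of per-chain matrices with columns `alpha`, `beta`,
#'   `sigma_phylo`, `sigma_resid`, `r2`.
#' @return An object of class `"posterior_summary"`: `beta_mean`, `ci_low`,
#'   `ci_high` (95% equal-tailed), `bayes_r2`, `p_d`, `rhat_max`,
#'   `n_draws`, plus posterior means of the SDs. Chains are attached as
#'   attribute `"draws"`.
#' @export
posterior_summaries <- function(draws) {
  stopifnot(is.list(draws), length(draws) >= 1)
  all_draws <- do.call(rbind, draws)
  beta <- all_draws[, "beta"]
  bm <- mean(beta)
  ci <- unname(quantile(beta, c(0.025, 0.975)))
  p_d <- if (bm == 0) 0.5 else max(mean(sign(beta) == sign(bm)), 0.5)
  if (length(draws) >= 2) {
    rhat_max <- max(vapply(colnames(all_draws), function(p)
      split_rhat(lapply(draws, function(d) d[, p])), 1.0))
  } else {
    warning("single chain: R-hat undefined")
    rhat_max <- NA_real_
  }
  out <- structure(list(
    beta_mean = bm, ci_low = ci[1], ci_high = ci[2],
    bayes_r2 = mean(all_draws[, "r2"]), p_d = p_d,
    rhat_max = rhat_max, n_draws = nrow(all_draws),
    alpha_mean = mean(all_draws[, "alpha"]),
    sigma_phylo = mean(all_draws[, "sigma_phylo"]),
    sigma_resid = mean(all_draws[, "sigma_resid"])),
    class = "posterior_summary")
  if (!is.na(rhat_max) && rhat_max >= 1.01)
    warning("rhat_max >= 1.01; chains may not have converged")
  attr(out, "draws") <- draws
  out
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic regression: beta = %.3f [%.3f, %.3f], Bayesian R2 = %.2f, p_d = %.2f\n  (%d draws, max split R-hat = %s)\n",
    x$beta_mean, x$ci_low, x$ci_high, x$bayes_r2, x$p_d, x$n_draws,
    if (is.na(x$rhat_max)) "NA" else sprintf("%.4f", x$rhat_max)))
  invisible(x)
}
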