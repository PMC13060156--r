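test_that("filter_min_eggs keeps the 10-embryo boundary inclusive", {
  rec <- data.frame(eggs_total = c(3, 10, 25), eggs_hatched = c(1, 5, 20))
  expect_equal(filter_min_eggs(rec)$eggs_total, c(10, 25))
  expect_equal(nrow(filter_min_eggs(rec[0, ])), 0)

  # recount oracle on simulated totals
  d <- build_design(list(strains = "wA", temperatures = 23,
                         cross_types = "ci", replicates_per_cell = 1000))
  p <- sim_params(cell_logit_mean = c("wA|23|ci" = 0), egg_count_mean = 30,
                  seed = 71)
  cr <- simulate_crosses(d, p)
  expect_equal(nrow(filter_min_eggs(cr)), sum(cr$eggs_total >= 10))
  expect_equal(filter_min_eggs(cr)$replicate_id,
               cr$replicate_id[cr$eggs_total >= 10])
})

test_that("marginal log-likelihood matches its degenerate and quadrature oracles", {
  rec <- data.frame(strain = "wA", temperature_c = 23, cross_type = "ci",
                    eggs_total = c(20, 15, 30), eggs_hatched = c(7, 0, 22))
  eta <- c("wA|23|ci" = 0.3)

  # sigma = 0, pi = 0: plain binomial log-likelihood exactly
  ll <- zib_marginal_loglik(list(eta = eta, sigma = 0, pi = 0), rec)
  expect_equal(ll, sum(dbinom(rec$eggs_hatched, rec$eggs_total,
                              plogis(0.3), log = TRUE)))

  # pi = 1 with all-zero outcomes: probability one
  rec0 <- transform(rec, eggs_hatched = 0)
  expect_equal(zib_marginal_loglik(list(eta = eta, sigma = 0, pi = 1), rec0),
               0)

  # brute-force trapezoid oracle over u in [-8 sigma, 8 sigma]
  sig <- 0.8
  rec1 <- rec[1, ]
  u <- seq(-8 * sig, 8 * sig, length.out = 10000)
  integrand <- dbinom(7, 20, plogis(0.3 + u)) * dnorm(u, 0, sig)
  oracle <- log(sum((integrand[-1] + integrand[-length(u)]) / 2 * diff(u)))
  got <- zib_marginal_loglik(list(eta = eta, sigma = sig, pi = 0), rec1,
                             quad_order = 40)
  expect_lt(abs(got - oracle), 1e-6)

  expect_error(zib_marginal_loglik(list(eta = eta, sigma = 0, pi = 0),
                                   transform(rec, strain = "wX")),
               "no logit mean")
  expect_error(zib_marginal_loglik(list(eta = eta, sigma = 0, pi = 0), rec,
                                   quad_order = 3), "quad_order")
})

# one moderately large sigma = 0 dataset shared by the next two tests
d0 <- small_design(reps = 150)
p0 <- small_params(d0, olre_sigma = 0, zi_prob = 0, seed = 81)
cr0 <- filter_min_eggs(simulate_crosses(d0, p0))
fit0 <- fit_zib_glmm(cr0, quad_order = 25, n_starts = 1)

test_that("with no overdispersion the fit reproduces plain logistic regression", {
  # independent implementation: glm on the saturated cell factor
  cell <- factor(key3(cr0$strain, cr0$temperature_c, cr0$cross_type))
  g <- glm(cbind(eggs_hatched, eggs_total - eggs_hatched) ~ 0 + cell,
           family = binomial(), data = cr0)
  gc <- setNames(coef(g), levels(cell))
  expect_lt(fit0$olre_sigma, 0.05)  # sigma near its boundary
  expect_lt(max(abs(fit0$cell_coef[names(gc)] - gc)), 1e-3)

  # EMMs equal the empirical logit of the pooled cell hatch fraction
  emm <- emm_cells(fit0)
  pooled <- tapply(cr0$eggs_hatched, cell, sum) /
    tapply(cr0$eggs_total, cell, sum)
  expect_lt(max(abs(emm$estimate[match(names(pooled), emm$cell)] -
                    qlogis(pooled))), 1e-3)
  expect_true(all(emm$se >= 0))
})

test_that("odds-ratio contrasts behave like odds arithmetic", {
  # identity contrast
  id <- odds_ratio_contrast(fit0, "wA|20|ci", "wA|20|ci")
  expect_equal(id$ratio, 1)
  expect_equal(id$p_raw, 1)

  # transitivity on the log scale is exact
  ab <- odds_ratio_contrast(fit0, "wA|20|ci", "wA|26|ci")$log_estimate
  bc <- odds_ratio_contrast(fit0, "wA|26|ci", "wB|20|ci")$log_estimate
  ac <- odds_ratio_contrast(fit0, "wA|20|ci", "wB|20|ci")$log_estimate
  expect_equal(ac, ab + bc)

  # true hatch 0.2 (ci) vs 0.8 (compatible): OR converges to 1/16
  d <- build_design(list(strains = "wA", temperatures = 23,
                         cross_types = c("compatible", "ci"),
                         replicates_per_cell = 600))
  p <- sim_params(cell_logit_mean = c("wA|23|compatible" = qlogis(0.8),
                                      "wA|23|ci" = qlogis(0.2)),
                  olre_sigma = 0, zi_prob = 0, egg_count_mean = 40,
                  seed = 82)
  f <- fit_zib_glmm(filter_min_eggs(simulate_crosses(d, p)),
                    quad_order = 15, n_starts = 1)
  orr <- odds_ratio_contrast(f, "wA|23|ci", "wA|23|compatible")
  expect_lt(abs(log(orr$ratio) - log(1 / 16)), 0.15)
  expect_true(orr$ci_low <= orr$ratio && orr$ratio <= orr$ci_high)
  expect_error(odds_ratio_contrast(f, "wX|23|ci", "wA|23|compatible"),
               "unknown cell")
})

test_that("ratio of odds ratios composes per-temperature CI contrasts", {
  # equal OR at both temperatures: ratio 1 (construct via equal gaps)
  L <- ratio_of_odds_ratios(fit0,
                            c("wB|20|ci", "wB|20|compatible"),
                            c("wB|26|ci", "wB|26|compatible"))
  or20 <- odds_ratio_contrast(fit0, "wB|20|ci", "wB|20|compatible")
  or26 <- odds_ratio_contrast(fit0, "wB|26|ci", "wB|26|compatible")
  expect_equal(L$log_estimate, or20$log_estimate - or26$log_estimate)

  # published per-temperature odds ratios reconstruct published ratios
  expect_equal(signif(or_ci_t(4.8e-3, 1.27), 2), 3.8e-3)
  expect_equal(signif(or_ci_t(7.1e-3, 0.12), 2), 0.059)
  expect_error(or_ci_t(-1, 2), "positive")
})

test_that("zero-inflated fit falls back when pi is unidentifiable", {
  # high hatch everywhere: no zero replicates, pi has no information
  d <- small_design(reps = 40)
  p <- default_sim_params(d, cell_logit_mean = cell_logits_from_or(d, 2.5),
                          olre_sigma = 0.3, zi_prob = 0, seed = 83)
  cr <- filter_min_eggs(simulate_crosses(d, p))
  expect_true(all(cr$eggs_hatched > 0))
  f <- fit_zib_glmm(cr, quad_order = 15, n_starts = 1)
  expect_false(f$zero_inflated)
  expect_equal(f$zi_prob, 0)
  expect_true(f$converged)
})

test_that("type-II Wald tests respect marginality and match balance oracles", {
  tw <- suppressWarnings(typeII_wald_tests(fit0))
  expect_equal(nrow(tw), 7)
  expect_true(all(tw$df[tw$term %in% c("strain", "temperature_c",
                                       "cross_type")] == 1))
  # dominant predictor is cross type (large simulated logit gap)
  expect_equal(tw$term[which.max(tw$chisq)], "cross_type")

  # independent oracle: on a complete balanced design the type-II statistic
  # equals the Wald test of the sum-contrast coefficient block obtained by
  # inverting the saturated cell-level design matrix (type-III construction)
  cells <- emm_cells(fit0)
  for (f in c("strain", "temperature_c", "cross_type"))
    cells[[f]] <- factor(cells[[f]])
  Xc <- model.matrix(~ strain * temperature_c * cross_type, data = cells,
                     contrasts.arg = list(strain = "contr.sum",
                                          temperature_c = "contr.sum",
                                          cross_type = "contr.sum"))
  beta <- solve(Xc, cells$estimate)
  Vb <- solve(Xc) %*% fit0$vcov[cells$cell, cells$cell] %*% t(solve(Xc))
  asg <- attr(Xc, "assign")
  labs <- attr(terms(~ strain * temperature_c * cross_type), "term.labels")
  for (k in seq_along(labs)) {
    idx <- which(asg == k)
    w <- drop(t(beta[idx]) %*% solve(Vb[idx, idx, drop = FALSE]) %*%
              beta[idx])
    expect_equal(tw$chisq[tw$term == labs[k]], w, tolerance = 1e-6)
  }
})

test_that("partial eta-squared follows its defining formula", {
  expect_equal(round(partial_eta_sq(1125.85, 1339), 2), 0.46)
  expect_equal(round(partial_eta_sq(145.88, 1339), 2), 0.10)
  expect_equal(partial_eta_sq(0, 500), 0)
  expect_error(partial_eta_sq(-1, 10), "nonnegative")
  expect_error(partial_eta_sq(5, 0), "n must be")
})

test_that("Benjamini-Hochberg adjustment is monotone and order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- c(0.001, 0.2, 0.04, 0.9, 0.03)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_fdr(p[perm]), adj[perm])
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
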