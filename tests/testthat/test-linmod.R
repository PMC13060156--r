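make_tab <- function(means, n_per_cell, sd, seed) {
  # means: named matrix strains x temperatures of true log2 values
  set.seed(seed)
  g <- expand.grid(strain = rownames(means), temperature_c = colnames(means),
                   rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  g$value_log2 <- means[cbind(g$strain, g$temperature_c)] +
    rnorm(nrow(g), 0, sd)
  g
}

test_that("factorial OLS recovers cell means and flags degenerate input", {
  tab <- data.frame(strain = rep(c("a", "b"), each = 3),
                    temperature_c = "23",
                    value_log2 = c(1, 1, 1, 5, 5, 5))
  f <- fit_factorial_ols(tab, "value_log2", "strain")
  expect_equal(unname(f$coef), c(1, 5))
  expect_equal(f$residual_var, 0)
  expect_equal(f$df_resid, 4)

  # constant response: every cell mean equals the constant
  tabc <- transform(tab, value_log2 = 2.5)
  fc <- fit_factorial_ols(tabc, "value_log2", "strain")
  expect_equal(unname(fc$coef), c(2.5, 2.5))

  # empty cell is an error naming the cell
  tab2 <- data.frame(strain = c("a", "a", "b"), temperature_c = c(1, 2, 1),
                     value_log2 = 1:3)
  expect_error(fit_factorial_ols(tab2, "value_log2",
                                 c("strain", "temperature_c")),
               "b|2", fixed = TRUE)
  expect_error(fit_factorial_ols(data.frame(strain = c("a", "b"),
                                            value_log2 = c(1, 2)),
                                 "value_log2", "strain"),
               "residual")
})

test_that("OLS recovery: known 8x4 cell means found within 3 SE", {
  means <- matrix(rnorm(32, 0, 2), 8, 4,
                  dimnames = list(paste0("s", 1:8), paste0("t", 1:4)))
  hits <- 0; total <- 0
  for (r in 1:25) {
    tab <- make_tab(means, 3, 0.5, seed = 100 + r)
    f <- fit_factorial_ols(tab, "value_log2", c("strain", "temperature_c"))
    keys <- names(f$coef)
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    truth <- means[cbind(parts[, 1], parts[, 2])]
    se <- sqrt(diag(f$vcov))
    hits <- hits + sum(abs(f$coef - truth) <= 3 * se)
    total <- total + length(keys)
  }
  expect_gte(hits / total, 0.99)
})

test_that("type-II F tests equal type-I on balanced designs and calibrate", {
  means <- matrix(c(1, 2, 3, 1.5, 2.5, 3.5), 3, 2,
                  dimnames = list(c("a", "b", "c"), c("cool", "warm")))
  tab <- make_tab(means, 4, 0.6, seed = 200)
  f <- fit_factorial_ols(tab, "value_log2", c("strain", "temperature_c"))
  a2 <- typeII_anova_F(f)
  # type-I oracle: base R sequential ANOVA
  a1 <- anova(lm(value_log2 ~ strain * temperature_c, data = tab))
  expect_equal(a2$ss, a1$`Sum Sq`[1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(a2$F, a1$`F value`[1:3], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(a2$df, a1$Df[1:3])

  # pure-noise calibration at alpha = 0.05
  set.seed(201)
  rej <- replicate(400, {
    tabn <- make_tab(means * 0, 3, 1, seed = sample.int(1e6, 1))
    an <- typeII_anova_F(fit_factorial_ols(tabn, "value_log2",
                                           c("strain", "temperature_c")))
    an$p[an$term == "strain"] < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  # interaction-free truth: interaction F has mean ~ 1
  set.seed(202)
  Fs <- replicate(150, {
    taba <- make_tab(outer(c(0, 1, 2), c(0, 3), `+`) |>
                       `dimnames<-`(list(c("a", "b", "c"), c("x", "y"))),
                     3, 1, seed = sample.int(1e6, 1))
    an <- typeII_anova_F(fit_factorial_ols(taba, "value_log2",
                                           c("strain", "temperature_c")))
    an$F[an$term == "strain:temperature_c"]
  })
  # null F_{2,12} has mean df2/(df2-2) = 1.2
  expect_lt(abs(mean(Fs) - 1.2), 0.35)
})

test_that("partial omega-squared matches its formula and edge cases", {
  # effect at noise level: zero
  expect_equal(as.numeric(partial_omega_sq(2 * 1.5, 2, 1.5, 30)), 0)
  # vanishing error mean square with signal: limit 1
  expect_equal(as.numeric(partial_omega_sq(5, 2, 0, 30)), 1)
  # negative raw values floored at 0 but retained
  o <- partial_omega_sq(0.5, 2, 1.5, 30)
  expect_equal(as.numeric(o), 0)
  expect_lt(attr(o, "raw"), 0)
  expect_error(partial_omega_sq(1, 1, -0.1, 10), "nonnegative")

  # recovery: strain means drawn from N(0, tau^2) with tau = sigma = 1;
  # closed-form expectation of the omega statistic with a = 8 strains,
  # n = 12 obs/strain, N = 96: (a-1) n tau^2 / ((a-1) n tau^2 + N sigma^2)
  set.seed(210)
  vals <- replicate(60, {
    means <- matrix(rnorm(8, 0, 1), 8, 2,
                    dimnames = list(paste0("s", 1:8), c("x", "y")))
    tab <- make_tab(means, 6, 1, seed = sample.int(1e6, 1))
    an <- typeII_anova_F(fit_factorial_ols(tab, "value_log2",
                                           c("strain", "temperature_c")))
    an$omega_sq_p[an$term == "strain"]
  })
  expected <- (7 * 12) / (7 * 12 + 96)
  expect_lt(abs(mean(vals) - expected), 0.05)
})

test_that("pairwise RR contrasts back-transform log2 differences", {
  means <- matrix(c(3, 3, 2, 3, 1, 3), 1, 6,
                  dimnames = list("sA", paste0("t", 1:6)))
  tab <- make_tab(means[, 1:2, drop = FALSE], 5, 0, seed = 300)
  f <- fit_factorial_ols(tab, "value_log2", c("strain", "temperature_c"))
  rr <- emm_pairwise_rr(f, "sA", "temperature_c")
  expect_equal(rr$ratio, 1)  # equal EMMs

  # EMM difference of 1 on log2 scale: RR = 2; antisymmetry under reversal
  tab2 <- make_tab(matrix(c(3, 2), 1, 2,
                          dimnames = list("sA", c("t1", "t2"))),
                   5, 0.001, seed = 301)
  f2 <- fit_factorial_ols(tab2, "value_log2", c("strain", "temperature_c"))
  rr2 <- emm_pairwise_rr(f2, "sA", "temperature_c")
  expect_equal(rr2$ratio, 2, tolerance = 0.01)
  expect_equal(rr2$ratio, 2^rr2$log_estimate)
  expect_true(rr2$ci_low <= rr2$ratio && rr2$ratio <= rr2$ci_high)

  # recovery study: generating density ratio 0.25 between temperatures
  set.seed(302)
  rrs <- replicate(200, {
    tabr <- make_tab(matrix(c(0, 2), 1, 2,
                            dimnames = list("sA", c("18", "26"))),
                     3, 0.4, seed = sample.int(1e6, 1))
    fr <- fit_factorial_ols(tabr, "value_log2", c("strain", "temperature_c"))
    emm_pairwise_rr(fr, "sA", "temperature_c")$ratio
  })
  expect_gte(median(rrs), 0.2)
  expect_lte(median(rrs), 0.31)
})

test_that("rank order survives the logit-to-linear route", {
  # sigma = 0 hatch data with well-separated cell means, logit-transformed
  # and refitted by OLS: identical cell ordering
  d <- small_design(reps = 80)
  p <- small_params(d, olre_sigma = 0, zi_prob = 0, seed = 310)
  p$cell_logit_mean <- setNames(seq(-2.1, 1.4, by = 0.5),
                                names(p$cell_logit_mean))
  cr <- filter_min_eggs(simulate_crosses(d, p))
  cr$frac <- (cr$eggs_hatched + 0.5) / (cr$eggs_total + 1)
  cr$logit <- qlogis(cr$frac)
  cr$cell <- key3(cr$strain, cr$temperature_c, cr$cross_type)
  f <- fit_factorial_ols(cr, "logit", "cell")
  fit <- fit_zib_glmm(cr, quad_order = 10, n_starts = 1)
  expect_equal(order(f$coef[names(fit$cell_coef)]),
               order(fit$cell_coef))
})
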