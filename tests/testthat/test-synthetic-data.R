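test_that("build_design validates and enumerates cells", {
  d <- build_design(list(strains = "wA", temperatures = 23,
                         cross_types = c("compatible", "ci")))
  expect_equal(nrow(expand_cells(d)), 2)

  full <- build_design(list(
    strains = paste0("s", 1:8), temperatures = c(18, 20, 23, 26),
    cross_types = c("compatible", "ci", "rescue"),
    drop_cells = data.frame(strain = c("s1", "s2"),
                            temperature = c(18, 20))))
  # enumeration oracle: 8*4 strain-temp cells minus 2 dropped, times 3 crosses
  expect_equal(nrow(expand_cells(full)), (8 * 4 - 2) * 3)
  expect_equal(nrow(full$cells), 30)

  expect_error(build_design(list(strains = "wA", temperatures = numeric(0),
                                 cross_types = "ci")),
               "temperature")
  expect_error(build_design(list(strains = c("wA", "wA"), temperatures = 23,
                                 cross_types = "ci")),
               "duplicate")
  # the study design: wTei misses one temperature, wTri two
  expect_equal(nrow(default_design()$cells), 8 * 4 - 3)
})

test_that("all five generators are seed-deterministic", {
  d <- small_design(reps = 5)
  p <- small_params(d, seed = 99)
  expect_identical(simulate_crosses(d, p), simulate_crosses(d, p))
  expect_identical(simulate_devtimes(d, p), simulate_devtimes(d, p))
  expect_identical(simulate_cq(d, p), simulate_cq(d, p))
  expect_identical(simulate_ddpcr(d, p), simulate_ddpcr(d, p))
  expect_identical(simulate_chronogram(letters[1:8], seed = 7),
                   simulate_chronogram(letters[1:8], seed = 7))
  # different seeds give different data
  p2 <- small_params(d, seed = 100)
  expect_false(identical(simulate_crosses(d, p), simulate_crosses(d, p2)))
})

test_that("simulated hatch counts respect their support and moments", {
  d <- build_design(list(strains = "wA", temperatures = 23,
                         cross_types = "ci", replicates_per_cell = 10000))
  # sigma = 0, pi = 0, logit 0, near-fixed egg totals: mean fraction 1/2
  p <- sim_params(cell_logit_mean = c("wA|23|ci" = 0), olre_sigma = 0,
                  zi_prob = 0, egg_count_mean = 100,
                  egg_count_dispersion = 1e6, seed = 11)
  cr <- simulate_crosses(d, p)
  expect_true(all(cr$eggs_hatched >= 0 & cr$eggs_hatched <= cr$eggs_total))
  expect_true(all(cr$eggs_total >= 1))
  expect_lt(abs(mean(cr$eggs_hatched / cr$eggs_total) - 0.5), 0.01)

  # pi = 1: every replicate is a structural zero
  p1 <- sim_params(cell_logit_mean = c("wA|23|ci" = 0), zi_prob = 1,
                   seed = 12)
  expect_true(all(simulate_crosses(d, p1)$eggs_hatched == 0))

  # unknown cell is a configuration error
  p_bad <- sim_params(cell_logit_mean = c("wX|23|ci" = 0), seed = 1)
  expect_error(simulate_crosses(d, p_bad), "logit mean")
})

test_that("hatch-fraction variance matches a brute-force mixture oracle", {
  d <- build_design(list(strains = "wA", temperatures = 23,
                         cross_types = "ci", replicates_per_cell = 20000))
  p <- sim_params(cell_logit_mean = c("wA|23|ci" = 0), olre_sigma = 1,
                  zi_prob = 0, egg_count_mean = 50,
                  egg_count_dispersion = 1e6, seed = 21)
  cr <- simulate_crosses(d, p)
  v_pkg <- var(cr$eggs_hatched / cr$eggs_total)
  v_oracle <- var(brute_hatch_fractions(20000, 50, 0, 1, 0, seed = 22))
  expect_lt(abs(v_pkg - v_oracle) / v_oracle, 0.05)
})

test_that("structural-zero fraction converges to its mixture probability", {
  d <- build_design(list(strains = "wA", temperatures = 23,
                         cross_types = "ci", replicates_per_cell = 30000))
  eta <- qlogis(0.3)
  p <- sim_params(cell_logit_mean = setNames(eta, "wA|23|ci"),
                  olre_sigma = 0, zi_prob = 0.1, egg_count_mean = 12,
                  egg_count_dispersion = 1e6, seed = 31)
  cr <- simulate_crosses(d, p)
  expected <- 0.1 + 0.9 * (1 - 0.3)^12
  expect_lt(abs(mean(cr$eggs_hatched == 0) - expected), 0.01)
})

test_that("development times follow the grid and the cytotype effect", {
  d <- small_design(reps = 2)
  # sd = 0, no cytotype effect: cytotypes identical
  p0 <- small_params(d, devtime_sd = 0, devtime_cyto_effect = 0,
                     devtime_reps = 4L, seed = 41)
  dv <- simulate_devtimes(d, p0)
  sym <- dv[dv$cytotype == "symbiotic", c("strain", "temperature_c",
                                          "emergence_day")]
  apo <- dv[dv$cytotype == "aposymbiotic", c("strain", "temperature_c",
                                             "emergence_day")]
  expect_equal(sym$emergence_day, apo$emergence_day)
  expect_true(all(dv$emergence_day %% 2 == 0))  # grid: even days
  expect_true(all(dv$emergence_day >= 1))

  # cytotype effect -3.6 days, sd 0: grid-snapped delta within one step
  p1 <- small_params(d, devtime_sd = 0, devtime_cyto_effect = -3.6,
                     devtime_reps = 50L, seed = 42)
  dv1 <- simulate_devtimes(d, p1)
  m <- tapply(dv1$emergence_day, dv1$cytotype, mean)
  delta <- m[["symbiotic"]] - m[["aposymbiotic"]]
  expect_lte(abs(delta - (-3.6)), 2)

  # latent times already on the grid: snapping is the identity
  expect_identical(snap_to_grid(c(2, 4, 10)), c(2L, 4L, 10L))
  expect_identical(snap_to_grid(c(1.1, 2.5)), c(2L, 4L))
  expect_error(small_params(d, devtime_sd = -1), "devtime_sd")
})

test_that("qPCR simulation encodes true densities in Cq space", {
  d <- build_design(list(strains = "wA", temperatures = 23,
                         cross_types = "ci"))
  # zero noise: target Cq = reference - log2 density exactly
  p <- small_params(d, cq_noise_sd = 0, cq_reps = 1L, seed = 51)
  p$cq_log2_wolbachia <- c("wA|23" = 3)
  p$cq_wovirus <- NULL
  cq <- simulate_cq(d, p)
  ref <- as.numeric(cq[cq$target == "host_reference", c("cq1", "cq2", "cq3")])
  fz <- as.numeric(cq[cq$target == "ftsZ", c("cq1", "cq2", "cq3")])
  expect_equal(unique(ref - fz), 3)
  expect_equal(cq_to_fold(fz, ref)$fold, 8)  # 2^3

  # lognormal bias of the mean recovered fold under Cq noise:
  # DeltaCq ~ Normal(-d, v) with v = (1 + 2/3) s^2 for triplicate means,
  # so E[2^-DeltaCq] = 2^d * exp((ln 2)^2 v / 2)
  d2 <- build_design(list(strains = "wA", temperatures = 23,
                          cross_types = "ci"))
  s <- 0.2
  p2 <- small_params(d2, cq_noise_sd = s, cq_reps = 1000L, seed = 52)
  p2$cq_log2_wolbachia <- c("wA|23" = 2)
  p2$cq_wovirus <- NULL
  cq2 <- simulate_cq(d2, p2)
  folds <- vapply(unique(cq2$sample_id), function(sid) {
    sub <- cq2[cq2$sample_id == sid, ]
    cq_to_fold(as.numeric(sub[sub$target == "ftsZ", c("cq1", "cq2", "cq3")]),
               as.numeric(sub[sub$target == "host_reference",
                              c("cq1", "cq2", "cq3")]))$fold
  }, 1.0)
  v <- (1 + 2 / 3) * s^2
  expected_mean <- 2^2 * exp((log(2))^2 * v / 2)
  expect_gt(mean(folds), 4)  # biased above the true fold
  expect_lt(abs(mean(folds) - expected_mean) / expected_mean, 0.05)
})

test_that("ddPCR simulation recovers true abundances", {
  d <- small_design()
  tab <- data.frame(variant = rep("v1", 2), treatment = c("cool", "warm"),
                    log2_abundance = c(3, 2))
  # zero noise: ratio is exactly 2^abundance
  p <- small_params(d, ddpcr_log_sd = 0, ddpcr_reps = 2L,
                    ddpcr_log2_abundance = tab, seed = 61)
  dd <- simulate_ddpcr(d, p)
  expect_equal(dd$conc_target / dd$conc_spike,
               2^tab$log2_abundance[rep(1:2, each = 2)])

  # cool - warm difference of 1 on log2 scale: fold-change 2 downstream
  ab <- spikein_abundance(dd$conc_target, dd$conc_spike)
  lm2 <- tapply(log2(ab), dd$treatment, mean)
  expect_equal(unname(2^(lm2[["cool"]] - lm2[["warm"]])), 2)

  # noisy replication: OLS recovers the true difference within 2 SE
  p2 <- small_params(d, ddpcr_log_sd = 0.3, ddpcr_reps = 500L,
                     ddpcr_log2_abundance = tab, seed = 62)
  dd2 <- simulate_ddpcr(d, p2)
  y <- log2(spikein_abundance(dd2$conc_target, dd2$conc_spike))
  fit <- lm(y ~ factor(dd2$treatment, levels = c("warm", "cool")))
  est <- coef(summary(fit))[2, ]
  expect_lt(abs(est["Estimate"] - 1), 2 * est["Std. Error"])
})

test_that("simulated chronograms are ultrametric with unit height", {
  nw <- simulate_chronogram(c("A", "B"), seed = 5)
  tr <- ape::read.tree(text = nw)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  depths <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(depths, c(1, 1), tolerance = 1e-9)

  nw8 <- simulate_chronogram(paste0("s", 1:8), seed = 6)
  tr8 <- ape::read.tree(text = nw8)
  d8 <- ape::node.depth.edgelength(tr8)[1:8]
  expect_true(all(abs(d8 - 1) < 1e-9))
  expect_identical(nw8, simulate_chronogram(paste0("s", 1:8), seed = 6))
  expect_error(simulate_chronogram("one", seed = 1), "2 strains")
})

test_that("write_simulated_inputs emits all five files", {
  dir <- withr::local_tempdir()
  d <- small_design(reps = 3)
  paths <- write_simulated_inputs(dir, d, small_params(d, devtime_reps = 2L,
                                                       cq_reps = 1L,
                                                       ddpcr_reps = 2L))
  expect_true(all(file.exists(paths)))
  cr <- read.csv(paths["crosses"])
  expect_named(cr, c("strain", "temperature_c", "cross_type", "eggs_total",
                     "eggs_hatched", "replicate_id"))
})
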