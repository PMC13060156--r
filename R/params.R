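#' Simulation parameters for the synthetic-data generators
#'
#' Collects every tunable of the five generators in one validated object.
#' Defaults are chosen to emulate the structure of a multi-strain CI
#' experiment: strongly bimodal hatch in CI crosses, mild extra-binomial
#' noise in compatible crosses, an every-other-day emergence grid, and
#' qPCR/ddPCR noise at bench-typical magnitudes.
#'
#' @param cell_logit_mean Named numeric vector of logit hatch probabilities,
#'   one per strain x temperature x cross cell, names built by
#'   [cell_logits_from_or()] / `paste(strain, temp, cross, sep = "|")`.
#' @param olre_sigma SD of the logit-scale observation-level random effect.
#' @param zi_prob Structural-zero probability shared across all cells.
#' @param egg_count_mean,egg_count_dispersion Mean and dispersion (negative
#'   binomial `size`) of eggs laid per replicate, truncated at 1.
#' @param devtime_base Latent development time (days) at the reference
#'   temperature for an aposymbiotic line.
#' @param devtime_temp_slope Days per degree C (negative: warmer is faster).
#' @param devtime_cyto_effect Additive shift (days) for symbiotic lines.
#' @param devtime_sd SD of the latent development time.
#' @param devtime_ref_temp Reference temperature for the slope (degrees C).
#' @param devtime_grid_phase Day offset of the every-other-day monitoring
#'   grid (0 = checks on even days after transfer).
#' @param devtime_reps Vials per strain x temperature x cytotype cell.
#' @param cq_ref_mean,cq_noise_sd Mean host-reference Cq and per-draw Cq
#'   noise SD (cycles).
#' @param cq_reps qPCR biological replicates per strain x temperature cell.
#' @param cq_log2_wolbachia Named numeric vector (names `strain|temp`) of
#'   true log2 Wolbachia density relative to the host gene.
#' @param cq_wovirus Data.frame (`strain`, `variant`, `temperature`,
#'   `log2_density`) of true log2 Wovirus-per-Wolbachia densities.
#' @param ddpcr_log_mean,ddpcr_log_sd Meanlog/sdlog of the lognormal
#'   spike-in concentration (copies/uL) and of the multiplicative target
#'   noise.
#' @param ddpcr_reps ddPCR replicates per variant x treatment.
#' @param ddpcr_log2_abundance Data.frame (`variant`, `treatment`,
#'   `log2_abundance`) of true log2 cifB transcript abundance relative to
#'   the spike-in; `treatment` is `"cool"` or `"warm"`.
#' @param seed Master integer seed; each generator uses its own child
#'   stream via [child_seed()].
#' @return A validated list of class `"ci_sim_params"`.
#' @export
sim_params <- function(cell_logit_mean = NULL,
                       olre_sigma = 0.8,
                       zi_prob = 0.05,
                       egg_count_mean = 24,
                       egg_count_dispersion = 5,
                       devtime_base = 13,
                       devtime_temp_slope = -1.1,
                       devtime_cyto_effect = -0.4,
                       devtime_sd = 0.8,
                       devtime_ref_temp = 23,
                       devtime_grid_phase = 0,
                       devtime_reps = 8L,
                       cq_ref_mean = 22,
                       cq_noise_sd = 0.3,
                       cq_reps = 3L,
                       cq_log2_wolbachia = NULL,
                       cq_wovirus = NULL,
                       ddpcr_log_mean = log(50),
                       ddpcr_log_sd = 0.3,
                       ddpcr_reps = 9L,
                       ddpcr_log2_abundance = NULL,
                       seed = 1L) {
  assert_nonneg(olre_sigma, "olre_sigma")
  assert_prob(zi_prob, "zi_prob")
  if (egg_count_mean <= 0 || egg_count_dispersion <= 0)
    stop_config("egg count mean and dispersion must be positive")
  assert_nonneg(devtime_sd, "devtime_sd")
  assert_nonneg(cq_noise_sd, "cq_noise_sd")
  assert_nonneg(ddpcr_log_sd, "ddpcr_log_sd")
  p <- list(cell_logit_mean = cell_logit_mean, olre_sigma = olre_sigma,
            zi_prob = zi_prob, egg_count_mean = egg_count_mean,
            egg_count_dispersion = egg_count_dispersion,
            devtime_base = devtime_base,
            devtime_temp_slope = devtime_temp_slope,
            devtime_cyto_effect = devtime_cyto_effect,
            devtime_sd = devtime_sd, devtime_ref_temp = devtime_ref_temp,
            devtime_grid_phase = devtime_grid_phase,
            devtime_reps = as.integer(devtime_reps),
            cq_ref_mean = cq_ref_mean, cq_noise_sd = cq_noise_sd,
            cq_reps = as.integer(cq_reps),
            cq_log2_wolbachia = cq_log2_wolbachia, cq_wovirus = cq_wovirus,
            ddpcr_log_mean = ddpcr_log_mean, ddpcr_log_sd = ddpcr_log_sd,
            ddpcr_reps = as.integer(ddpcr_reps),
            ddpcr_log2_abundance = ddpcr_log2_abundance,
            seed = as.integer(seed))
  class(p) <- "ci_sim_params"
  p
}

#' Convert per-cell odds ratios to cell logit means
#'
#' CI strength is most naturally specified as an odds ratio against the
#' compatible cross of the same strain-temperature cell. This helper turns
#' a table of compatible-cross logits and CI/rescue odds ratios into the
#' flat `cell_logit_mean` vector the cross simulator consumes.
#'
#' @param design A `"ci_design"`.
#' @param compat_logit Single logit hatch probability for compatible
#'   crosses, or a named vector keyed `strain|temp`.
#' @param or_ci Named vector (names `strain|temp`) of CI odds ratios.
#' @param or_rescue Named vector of rescue odds ratios; defaults to 1
#'   (complete rescue) where unnamed.
#' @return Named numeric vector of logits keyed `strain|temp|cross`.
#' @export
cell_logits_from_or <- function(design, compat_logit = 1.5,
                                or_ci = NULL, or_rescue = NULL) {
  cells <- expand_cells(design)
  st <- cell_key(cells$strain, cells$temperature)
  base <- if (length(compat_logit) == 1 && is.null(names(compat_logit)))
    setNames(rep(compat_logit, length(st)), st) else compat_logit[st]
  or <- rep(1, nrow(cells))
  pick <- function(tab) {
    v <- rep(1, nrow(cells))
    if (!is.null(tab)) {
      hit <- st %in% names(tab)
      v[hit] <- tab[st[hit]]
    }
    v
  }
  or[cells$cross_type == "ci"] <- pick(or_ci)[cells$cross_type == "ci"]
  or[cells$cross_type == "rescue"] <-
    pick(or_rescue)[cells$cross_type == "rescue"]
  eta <- base + log(or)
  setNames(eta, cell_key(cells$strain, cells$temperature, cells$cross_type))
}

# Default "true" CI odds ratios for the eight-strain design: four strains
# with temperature-sensitive CI (wMel, wTei, wRi, wHa), four resistant
# (wSeg, wCha, wBic, wTri). Magnitudes span the strong-to-absent CI range.
default_or_ci <- function() {
  tab <- rbind(
    c("wMel", 18, 0.024), c("wMel", 20, 7.1e-3), c("wMel", 23, 0.12),
    c("wMel", 26, 0.037),
    c("wTei", 20, 0.87), c("wTei", 23, 4.8e-3), c("wTei", 26, 1.27),
    c("wRi", 18, 6.1e-5), c("wRi", 20, 5.4e-5), c("wRi", 23, 1.9e-3),
    c("wRi", 26, 8.8e-5),
    c("wHa", 18, 2.0e-3), c("wHa", 20, 1.3e-2), c("wHa", 23, 5.0e-4),
    c("wHa", 26, 4.0e-4),
    c("wSeg", 18, 3e-3), c("wSeg", 20, 3e-3), c("wSeg", 23, 3e-3),
    c("wSeg", 26, 3e-3),
    c("wCha", 18, 6.1e-5), c("wCha", 20, 5.4e-5), c("wCha", 23, 2.9e-5),
    c("wCha", 26, 8.8e-5),
    c("wBic", 18, 1e-3), c("wBic", 20, 1e-3), c("wBic", 23, 1e-3),
    c("wBic", 26, 1e-3),
    c("wTri", 23, 2e-3), c("wTri", 26, 2e-3))
  setNames(as.numeric(tab[, 3]),
           cell_key(tab[, 1], as.numeric(tab[, 2])))
}

default_or_rescue <- function() {
  tab <- rbind(
    c("wRi", 20, 0.10), c("wRi", 26, 0.07),
    c("wCha", 20, 0.021), c("wBic", 23, 0.15), c("wHa", 23, 0.17))
  setNames(as.numeric(tab[, 3]),
           cell_key(tab[, 1], as.numeric(tab[, 2])))
}

# Default true log2 Wolbachia densities per strain-temperature cell:
# strain base levels dominate, with cold inhibition in wMel/wSeg/wRi/wHa
# and an intermediate-temperature peak in wBic.
default_log2_wolbachia <- function(design) {
  base <- c(wMel = 4, wTei = 3, wSeg = 5, wCha = 2.5, wBic = 3.5,
            wRi = 6, wTri = 4.5, wHa = 5.5)
  shift <- function(strain, temp) {
    cold <- c("wMel", "wSeg", "wRi", "wHa")
    if (strain %in% cold) 0.45 * (temp - 23) / 3
    else if (strain == "wBic") -0.8 * abs(temp - 20) / 3 + 0.5
    else 0
  }
  cells <- design$cells
  vals <- mapply(function(s, t) {
    b <- if (s %in% names(base)) base[[s]] else 4
    b + shift(s, t)
  }, cells$strain, cells$temperature)
  setNames(as.numeric(vals), cell_key(cells$strain, cells$temperature))
}

# Default true log2 Wovirus-per-Wolbachia densities. wBic carries no
# detectable Wovirus; wRi carries two variants.
default_wovirus_table <- function(design) {
  cells <- design$cells
  cells <- cells[cells$strain != "wBic", , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    s <- cells$strain[i]; t <- cells$temperature[i]
    nv <- if (s == "wRi") 2L else 1L
    data.frame(strain = s, variant = paste0(s, "_sr", seq_len(nv)),
               temperature = t,
               log2_density = -1 + 0.2 * (t - 23) / 3 - 0.3 * (seq_len(nv) - 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Default true log2 cifB transcript abundances (relative to spike-in) for
# the five assayed variants under cool and warm rearing. Four variants are
# more highly transcribed at the cooler temperature; one is insensitive.
default_ddpcr_table <- function() {
  v <- c("cifB_wMel_T1", "cifB_wRi_T1", "cifB_wRi_T2",
         "cifB_wHa_T1-1", "cifB_wHa_T1-2")
  warm <- c(1.0, 2.0, 1.5, 1.2, 0.8)
  # log2 RR (warm - cool): RR < 1 means more transcript when cool
  lrr <- log2(c(0.45, 0.18, 0.27, 0.32, 0.98))
  data.frame(variant = rep(v, 2),
             treatment = rep(c("warm", "cool"), each = length(v)),
             log2_abundance = c(warm, warm - lrr),
             stringsAsFactors = FALSE)
}

#' Default simulation parameters for a design
#'
#' Fills the per-cell truth tables (hatch logits, densities, transcript
#' abundances) with the package's default multi-strain scenario.
#'
#' @param design A `"ci_design"`, typically [default_design()].
#' @param ... Overrides passed on to [sim_params()].
#' @return A `"ci_sim_params"` object.
#' @export
default_sim_params <- function(design = default_design(), ...) {
  dots <- list(...)
  args <- list(
    cell_logit_mean = cell_logits_from_or(
      design, compat_logit = 1.5,
      or_ci = default_or_ci(), or_rescue = default_or_rescue()),
    cq_log2_wolbachia = default_log2_wolbachia(design),
    cq_wovirus = default_wovirus_table(design),
    ddpcr_log2_abundance = default_ddpcr_table())
  args[names(dots)] <- dots
  do.call(sim_params, args)
}
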