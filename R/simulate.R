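#' Simulate egg-lay cross replicates
#'
#' Draws one record per replicate of each strain x temperature x cross cell.
#' Egg totals follow a negative binomial truncated at 1. With probability
#' `zi_prob` a replicate is a structural zero (no eggs hatch); otherwise a
#' replicate-level logit deviation `u ~ Normal(0, olre_sigma^2)` is drawn
#' and hatched counts follow `Binomial(eggs_total, plogis(eta + u))`.
#'
#' @param design A `"ci_design"`.
#' @param params A `"ci_sim_params"`; `cell_logit_mean` must name every
#'   cell in the design.
#' @return A data.frame (`strain`, `temperature_c`, `cross_type`,
#'   `eggs_total`, `eggs_hatched`, `replicate_id`).
#' @export
simulate_crosses <- function(design, params) {
  stopifnot(inherits(design, "ci_design"), inherits(params, "ci_sim_params"))
  cells <- expand_cells(design)
  keys <- cell_key(cells$strain, cells$temperature, cells$cross_type)
  eta <- params$cell_logit_mean
  missing_eta <- setdiff(keys, names(eta))
  if (length(missing_eta))
    stop_config("no logit mean for cell(s): ",
                paste(utils::head(missing_eta, 5), collapse = "; "))
  reps <- design$replicates_per_cell
  n <- nrow(cells) * reps
  idx <- rep(seq_len(nrow(cells)), each = reps)

  with_seed(child_seed(params$seed, 1L), {
    eggs <- rnbinom(n, size = params$egg_count_dispersion,
                    mu = params$egg_count_mean)
    while (any(eggs == 0))  # truncate at >= 1 egg
      eggs[eggs == 0] <- rnbinom(sum(eggs == 0),
                                 size = params$egg_count_dispersion,
                                 mu = params$egg_count_mean)
    zi <- runif(n) < params$zi_prob
    u <- rnorm(n, 0, params$olre_sigma)
    p <- plogis(eta[keys[idx]] + u)
    hatched <- rbinom(n, eggs, p)
    hatched[zi] <- 0L
  })

  data.frame(strain = cells$strain[idx],
             temperature_c = cells$temperature[idx],
             cross_type = cells$cross_type[idx],
             eggs_total = as.integer(eggs),
             eggs_hatched = as.integer(hatched),
             replicate_id = paste0(keys[idx], "|r",
                                   rep(seq_len(reps), nrow(cells))),
             stringsAsFactors = FALSE)
}

#' Snap latent emergence times up to the monitoring grid
#'
#' Vials are checked every other day, so first emergence is observed at the
#' first check on or after the latent time.
#'
#' @param latent Numeric latent development times (days).
#' @param phase Day offset of the grid (default 0: checks at 2, 4, 6, ...).
#' @return Integer days on the grid, at least `max(1, phase)`.
#' @export
snap_to_grid <- function(latent, phase = 0) {
  out <- phase + 2 * ceiling((latent - phase) / 2)
  as.integer(pmax(out, max(1, phase)))
}

#' Simulate development-time records
#'
#' Latent time is linear in temperature with an additive cytotype shift,
#' plus Gaussian noise, then snapped up to the every-other-day grid.
#'
#' @inheritParams simulate_crosses
#' @return A data.frame (`strain`, `cytotype`, `temperature_c`,
#'   `emergence_day`).
#' @export
simulate_devtimes <- function(design, params) {
  stopifnot(inherits(design, "ci_design"), inherits(params, "ci_sim_params"))
  if (params$devtime_sd < 0) stop_config("devtime_sd must be >= 0")
  cells <- merge(design$cells,
                 data.frame(cytotype = c("aposymbiotic", "symbiotic"),
                            stringsAsFactors = FALSE))
  cells <- cells[order(cells$strain, cells$temperature, cells$cytotype), ]
  reps <- params$devtime_reps
  idx <- rep(seq_len(nrow(cells)), each = reps)
  mu <- params$devtime_base +
    params$devtime_temp_slope * (cells$temperature[idx] - params$devtime_ref_temp) +
    params$devtime_cyto_effect * (cells$cytotype[idx] == "symbiotic")
  with_seed(child_seed(params$seed, 2L), {
    latent <- mu + rnorm(length(idx), 0, params$devtime_sd)
  })
  data.frame(strain = cells$strain[idx],
             cytotype = cells$cytotype[idx],
             temperature_c = cells$temperature[idx],
             emergence_day = snap_to_grid(latent, params$devtime_grid_phase),
             stringsAsFactors = FALSE)
}

#' Simulate triplicate qPCR Cq records
#'
#' Per biological sample, the host-reference Cq is drawn around
#' `cq_ref_mean`; the Wolbachia marker (ftsZ) sits `log2 density` cycles
#' below the reference, and each Wovirus serine-recombinase variant sits
#' its own `log2 density` below ftsZ. Triplicates are independent draws
#' with SD `cq_noise_sd` around the sample-level value.
#'
#' @inheritParams simulate_crosses
#' @return A data.frame (`sample_id`, `strain`, `temperature_c`, `target`,
#'   `cq1`, `cq2`, `cq3`). Targets are `host_reference`, `ftsZ`, and one
#'   row per Wovirus variant.
#' @export
simulate_cq <- function(design, params) {
  stopifnot(inherits(design, "ci_design"), inherits(params, "ci_sim_params"))
  dw <- params$cq_log2_wolbachia
  if (is.null(dw)) stop_config("cq_log2_wolbachia truth table is required")
  cells <- design$cells
  keys <- cell_key(cells$strain, cells$temperature)
  missing_d <- setdiff(keys, names(dw))
  if (length(missing_d))
    stop_config("no log2 Wolbachia density for cell(s): ",
                paste(utils::head(missing_d, 5), collapse = "; "))
  wov <- params$cq_wovirus
  s <- params$cq_noise_sd
  rows <- list()
  with_seed(child_seed(params$seed, 3L), {
    for (i in seq_len(nrow(cells))) {
      for (r in seq_len(params$cq_reps)) {
        sid <- paste0(keys[i], "|s", r)
        ref <- rnorm(1, params$cq_ref_mean, s)
        ftsz <- ref - dw[[keys[i]]] + rnorm(1, 0, s)
        trip <- function(center) center + rnorm(3, 0, s)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, strain = cells$strain[i],
          temperature_c = cells$temperature[i],
          target = c("host_reference", "ftsZ"),
          rbind(trip(ref), trip(ftsz)), stringsAsFactors = FALSE)
        if (!is.null(wov)) {
          here <- wov[wov$strain == cells$strain[i] &
                      wov$temperature == cells$temperature[i], , drop = FALSE]
          for (j in seq_len(nrow(here))) {
            sr <- ftsz - here$log2_density[j] + rnorm(1, 0, s)
            rows[[length(rows) + 1]] <- data.frame(
              sample_id = sid, strain = cells$strain[i],
              temperature_c = cells$temperature[i],
              target = here$variant[j], rbind(trip(sr)),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  names(out)[5:7] <- c("cq1", "cq2", "cq3")
  rownames(out) <- NULL
  out
}

#' Simulate spike-in-normalized ddPCR concentrations
#'
#' Spike-in concentrations are lognormal; target concentrations are the
#' spike-in times `2^(true log2 abundance)` times multiplicative lognormal
#' noise.
#'
#' @inheritParams simulate_crosses
#' @return A data.frame (`variant`, `treatment`, `conc_target`,
#'   `conc_spike`).
#' @export
simulate_ddpcr <- function(design, params) {
  stopifnot(inherits(params, "ci_sim_params"))
  tab <- params$ddpcr_log2_abundance
  if (is.null(tab)) stop_config("ddpcr_log2_abundance truth table is required")
  reps <- params$ddpcr_reps
  idx <- rep(seq_len(nrow(tab)), each = reps)
  with_seed(child_seed(params$seed, 4L), {
    spike <- rlnorm(length(idx), params$ddpcr_log_mean, params$ddpcr_log_sd)
    noise <- rlnorm(length(idx), 0, params$ddpcr_log_sd)
  })
  data.frame(variant = tab$variant[idx], treatment = tab$treatment[idx],
             conc_target = spike * 2^tab$log2_abundance[idx] * noise,
             conc_spike = spike, stringsAsFactors = FALSE)
}

#' Simulate a relative chronogram over strains
#'
#' Draws a random coalescent (hence ultrametric) tree over the strain
#' labels and rescales it so every root-to-tip path has length 1, mirroring
#' a relative chronogram with root age fixed to 1.
#'
#' @param strains Character vector of two or more strain labels.
#' @param seed Integer seed.
#' @return A single newick string with branch lengths.
#' @export
simulate_chronogram <- function(strains, seed = 1L) {
  if (length(strains) < 2) stop_config("need at least 2 strains for a tree")
  if (anyDuplicated(strains)) stop_config("duplicate strain labels")
  tr <- with_seed(child_seed(seed, 5L),
                  ape::rcoal(length(strains), tip.label = strains))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  ape::write.tree(tr)
}

#' Write all simulated pipeline inputs to a directory
#'
#' Emits `crosses.csv`, `devtime.csv`, `cq.csv`, `ddpcr.csv` and
#' `chronogram.nwk` with the schemas the analysis stages consume.
#'
#' @inheritParams simulate_crosses
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_inputs <- function(dir, design = default_design(),
                                   params = default_sim_params(design)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(crosses = file.path(dir, "crosses.csv"),
             devtime = file.path(dir, "devtime.csv"),
             cq = file.path(dir, "cq.csv"),
             ddpcr = file.path(dir, "ddpcr.csv"),
             chronogram = file.path(dir, "chronogram.nwk"))
  write.csv(simulate_crosses(design, params), paths["crosses"],
            row.names = FALSE)
  write.csv(simulate_devtimes(design, params), paths["devtime"],
            row.names = FALSE)
  write.csv(simulate_cq(design, params), paths["cq"], row.names = FALSE)
  write.csv(simulate_ddpcr(design, params), paths["ddpcr"],
            row.names = FALSE)
  writeLines(simulate_chronogram(design$strains, params$seed),
             paths["chronogram"])
  invisible(paths)
}
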