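read_input_csv <- function(path, required_cols, stage) {
  if (!file.exists(path))
    stop_config("input file for stage '", stage, "' not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_col <- setdiff(required_cols, names(tab))
  if (length(missing_col))
    stop_config("file ", path, " lacks column(s): ",
                paste(missing_col, collapse = ", "))
  tab
}

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives a child stream.
#' @param simulate Generate synthetic inputs (default TRUE). If FALSE,
#'   `inputs` must name existing files.
#' @param inputs Named list of paths (`crosses`, `devtime`, `cq`, `ddpcr`,
#'   `chronogram`) used when `simulate = FALSE`.
#' @param stages Stages to run, a subset of
#'   `c("hatch", "devtime", "densities", "expression", "concordance",
#'   "phylo")`.
#' @param replicates_per_cell Egg-lay replicates per cell for simulation.
#' @param strains,temperatures Optional subsets of the default design's
#'   strains and temperatures, for reduced-scale runs.
#' @param quad_order,n_perm,n_mc,chains,iters,warmup Stage tunables.
#' @param n_starts Optimizer starts for the hatch model.
#' @return A validated list of class `"ci_pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            inputs = NULL,
                            stages = c("hatch", "devtime", "densities",
                                       "expression", "concordance", "phylo"),
                            replicates_per_cell = 15L, strains = NULL,
                            temperatures = NULL, quad_order = 40,
                            n_perm = 9999, n_mc = 10000, chains = 4,
                            iters = 8000, warmup = 2000, n_starts = 3) {
  known <- c("hatch", "devtime", "densities", "expression", "concordance",
             "phylo")
  bad <- setdiff(stages, known)
  if (length(bad)) stop_config("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!simulate) {
    need <- c("crosses", "devtime", "cq", "ddpcr", "chronogram")
    miss <- setdiff(need, names(inputs %||% list()))
    if (length(miss))
      stop_config("simulate = FALSE requires input paths: ",
                  paste(miss, collapse = ", "))
    absent <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(absent))
      stop_config("missing input file(s): ", paste(absent, collapse = ", "))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, stages = stages,
                 replicates_per_cell = replicates_per_cell,
                 strains = strains, temperatures = temperatures,
                 quad_order = quad_order, n_perm = n_perm, n_mc = n_mc,
                 chains = chains, iters = iters, warmup = warmup,
                 n_starts = n_starts),
            class = "ci_pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return A `"ci_pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

# --- stage implementations -------------------------------------------------

stage_hatch <- function(cfg, paths, out) {
  crosses <- read_input_csv(paths["crosses"],
                            c("strain", "temperature_c", "cross_type",
                              "eggs_total", "eggs_hatched"), "hatch")
  kept <- filter_min_eggs(crosses)
  n_dropped <- nrow(crosses) - nrow(kept)
  message("hatch: excluded ", n_dropped, " replicate(s) with < 10 embryos")
  fit <- with_seed(child_seed(cfg$seed, 30L),
                   fit_zib_glmm(kept, quad_order = cfg$quad_order,
                                n_starts = cfg$n_starts))
  emm <- emm_cells(fit)
  tests <- suppressWarnings(typeII_wald_tests(fit))

  # contrast families: OR_CI, OR_R, and OR_CI,T (per-strain temperature pairs)
  st_cells <- unique(emm[, c("strain", "temperature_c")])
  fam_ci <- list(); fam_r <- list(); fam_cit <- list()
  has_cell <- function(k) k %in% names(fit$cell_coef)
  for (i in seq_len(nrow(st_cells))) {
    s <- st_cells$strain[i]; t <- st_cells$temperature_c[i]
    ci_c <- cell_key(s, t, "ci"); co_c <- cell_key(s, t, "compatible")
    re_c <- cell_key(s, t, "rescue")
    if (has_cell(ci_c) && has_cell(co_c))
      fam_ci[[length(fam_ci) + 1]] <- odds_ratio_contrast(
        fit, ci_c, co_c, label = paste0("OR_CI ", s, " ", t, "C"))
    if (has_cell(re_c) && has_cell(co_c))
      fam_r[[length(fam_r) + 1]] <- odds_ratio_contrast(
        fit, re_c, co_c, label = paste0("OR_R ", s, " ", t, "C"))
  }
  for (s in unique(st_cells$strain)) {
    temps <- sort(st_cells$temperature_c[st_cells$strain == s])
    if (length(temps) < 2) next
    for (i in seq_along(temps)[-length(temps)]) for (j in seq(i + 1, length(temps))) {
      pc <- c(cell_key(s, temps[i], "ci"), cell_key(s, temps[i], "compatible"))
      pw <- c(cell_key(s, temps[j], "ci"), cell_key(s, temps[j], "compatible"))
      if (all(vapply(c(pc, pw), has_cell, TRUE)))
        fam_cit[[length(fam_cit) + 1]] <- ratio_of_odds_ratios(
          fit, pc, pw,
          label = paste0("OR_CI,T ", s, " ", temps[i], "C/", temps[j], "C"))
    }
  }
  families <- list(ci = fam_ci, rescue = fam_r, cit = fam_cit)
  contrasts <- do.call(rbind, lapply(names(families), function(nm) {
    fam <- families[[nm]]
    if (!length(fam)) return(NULL)
    res <- adjust_contrast_family(do.call(rbind, fam))
    res$family <- nm
    res
  }))

  write.table(contrasts, file.path(out, "contrasts.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(tests, file.path(out, "hatch_typeII.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(coefficients = as.list(fit$cell_coef), olre_sigma = fit$olre_sigma,
         zi_prob = fit$zi_prob, loglik = fit$loglik, n_obs = fit$n_obs,
         converged = fit$converged, zero_inflated = fit$zero_inflated),
    file.path(out, "fit.json"), auto_unbox = TRUE, digits = NA)
  list(fit = fit, emm = emm, tests = tests, contrasts = contrasts,
       summary = list(n_obs = fit$n_obs, loglik = fit$loglik,
                      olre_sigma = fit$olre_sigma, zi_prob = fit$zi_prob,
                      converged = fit$converged,
                      dominant_term = tests$term[which.max(tests$chisq)]))
}

stage_devtime <- function(cfg, paths, out) {
  dev <- read_input_csv(paths["devtime"],
                        c("strain", "cytotype", "temperature_c",
                          "emergence_day"), "devtime")
  terms <- c("temperature_c", "strain", "cytotype",
             "strain:temperature_c", "strain:cytotype",
             "cytotype:temperature_c", "strain:cytotype:temperature_c")
  pm <- permanova_seq(dev$emergence_day,
                      dev[, c("strain", "cytotype", "temperature_c")],
                      terms, n_perm = cfg$n_perm,
                      seed = child_seed(cfg$seed, 40L))
  pw <- pairwise_devtime_tests(dev, n_perm = 10000,
                               seed = child_seed(cfg$seed, 41L))
  write.table(pm, file.path(out, "permanova.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(pw$cytotype, file.path(out, "pairwise_permutation.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  list(permanova = pm, pairwise = pw,
       summary = list(
         temperature_r2 = pm$r2[pm$term == "temperature_c"],
         largest_delta_t = pw$cytotype$delta_t[
           which.max(abs(pw$cytotype$delta_t))]))
}

stage_densities <- function(cfg, paths, out) {
  cq <- read_input_csv(paths["cq"],
                       c("sample_id", "strain", "temperature_c", "target",
                         "cq1", "cq2", "cq3"), "densities")
  dens <- densities_from_cq(cq)
  write.csv(dens, file.path(out, "densities.csv"), row.names = FALSE)
  fits <- list(); anovas <- list(); rrs <- list()
  for (metric in unique(dens$metric)) {
    sub <- dens[dens$metric == metric, ]
    fit <- fit_factorial_ols(sub, "log2_fold",
                             c("strain", "temperature_c"),
                             allow_incomplete = TRUE)
    an <- suppressWarnings(typeII_anova_F(fit))
    an$metric <- metric
    anovas[[metric]] <- an
    rr <- do.call(rbind, lapply(unique(sub$strain), function(s) {
      if (length(unique(sub$temperature_c[sub$strain == s])) < 2) return(NULL)
      r <- emm_pairwise_rr(fit, s, "temperature_c")
      r$strain <- s; r$metric <- metric
      r
    }))
    rrs[[metric]] <- rr
    fits[[metric]] <- fit
  }
  anova_tab <- do.call(rbind, anovas)
  rr_tab <- do.call(rbind, rrs)
  write.table(anova_tab, file.path(out, "anova.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(rr_tab, file.path(out, "rr_contrasts.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  wa <- anovas[["wolbachia_per_host"]]
  list(densities = dens, fits = fits, anova = anova_tab, rr = rr_tab,
       summary = list(
         strain_omega_sq = wa$omega_sq_p[wa$term == "strain"],
         n_samples = length(unique(dens$sample_id))))
}

stage_expression <- function(cfg, paths, out) {
  dd <- read_input_csv(paths["ddpcr"],
                       c("variant", "treatment", "conc_target", "conc_spike"),
                       "expression")
  ab <- suppressWarnings(spikein_abundance(dd$conc_target, dd$conc_spike))
  keep <- ab > 0
  if (any(!keep))
    message("expression: excluded ", sum(!keep),
            " zero-target measurement(s)")
  tab <- data.frame(variant = dd$variant[keep],
                    treatment = dd$treatment[keep],
                    log2_abundance = log2(ab[keep]),
                    stringsAsFactors = FALSE)
  fit <- fit_factorial_ols(tab, "log2_abundance",
                           c("variant", "treatment"))
  an <- typeII_anova_F(fit)
  rr <- do.call(rbind, lapply(unique(tab$variant), function(v) {
    r <- emm_pairwise_rr(fit, v, "treatment")
    r$variant <- v
    r
  }))
  write.table(an, file.path(out, "expression_anova.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(rr, file.path(out, "expression_rr.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  list(table = tab, fit = fit, anova = an, rr = rr,
       summary = list(variant_omega_sq = an$omega_sq_p[an$term == "variant"],
                      n_measurements = nrow(tab)))
}

# EMM table of log OR_CI per strain-temperature cell from hatch contrasts
ci_strength_emm <- function(hatch) {
  ci <- hatch$contrasts[hatch$contrasts$family == "ci", ]
  parts <- do.call(rbind, strsplit(sub("^OR_CI ", "", ci$label), " "))
  data.frame(strain = parts[, 1],
             temperature_c = as.numeric(sub("C$", "", parts[, 2])),
             estimate = ci$log_estimate, se = ci$se,
             stringsAsFactors = FALSE)
}

# EMM table (mean log2 density + SE) per strain-temperature from an OLS fit
density_emm <- function(fit) {
  keys <- names(fit$coef)
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(strain = parts[, 1], temperature_c = as.numeric(parts[, 2]),
             estimate = unname(fit$coef), se = sqrt(diag(fit$vcov)),
             stringsAsFactors = FALSE)
}

stage_concordance <- function(cfg, state, out) {
  hatch <- state$results$hatch
  dens <- state$results$densities
  if (is.null(hatch) || is.null(dens))
    stop_config("concordance requires the hatch and densities stages")
  ci_emm <- ci_strength_emm(hatch)
  w_emm <- density_emm(dens$fits[["wolbachia_per_host"]])
  rows <- list()
  for (s in unique(ci_emm$strain)) {
    a <- ci_emm[ci_emm$strain == s, ]
    b <- w_emm[w_emm$strain == s, ]
    shared <- intersect(a$temperature_c, b$temperature_c)
    if (length(shared) < 2) next
    a <- a[match(shared, a$temperature_c), ]
    b <- b[match(shared, b$temperature_c), ]
    r <- mc_concordance(a$estimate, a$se, b$estimate, b$se,
                        n_mc = cfg$n_mc,
                        seed = child_seed(cfg$seed, 50L + match(s, unique(ci_emm$strain))))
    rows[[length(rows) + 1]] <- data.frame(
      pair = "ci_strength~wolbachia_density", strain = s, tau = r$tau,
      p_d = r$p_d, n_conditions = r$n_conditions, stringsAsFactors = FALSE)
  }
  conc <- do.call(rbind, rows)

  # within-strain Pearson correlations on raw log2 densities
  d <- dens$densities
  pear <- list()
  for (s in unique(d$strain)) {
    w <- d[d$strain == s & d$metric == "wolbachia_per_host", ]
    v <- d[d$strain == s & d$metric == "wovirus_per_wolbachia", ]
    shared <- intersect(w$sample_id, v$sample_id)
    if (length(shared) < 3) next
    r <- pearson_correlation(
      w$log2_fold[match(shared, w$sample_id)],
      v$log2_fold[match(shared, v$sample_id)])
    pear[[length(pear) + 1]] <- data.frame(
      strain = s, r = r$r, r_squared = r$r_squared, p = r$p, n = r$n,
      stringsAsFactors = FALSE)
  }
  pearson <- do.call(rbind, pear)
  write.table(conc, file.path(out, "concordance.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(pearson, file.path(out, "pearson.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  list(concordance = conc, pearson = pearson,
       summary = list(n_strains = nrow(conc),
                      mean_abs_tau = mean(abs(conc$tau))))
}

stage_phylo <- function(cfg, paths, state, out) {
  hatch <- state$results$hatch
  dens <- state$results$densities
  if (is.null(hatch) || is.null(dens))
    stop_config("phylo requires the hatch and densities stages")
  tree <- parse_newick_chronogram(paths["chronogram"])
  A <- phylo_covariance(tree)
  ci_emm <- ci_strength_emm(hatch)
  w_emm <- density_emm(dens$fits[["wolbachia_per_host"]])
  key <- paste(ci_emm$strain, ci_emm$temperature_c)
  wkey <- paste(w_emm$strain, w_emm$temperature_c)
  hit <- match(key, wkey)
  ok <- !is.na(hit)
  y <- ci_emm$estimate[ok]
  x <- w_emm$estimate[hit[ok]]
  strains <- ci_emm$strain[ok]
  post <- fit_phylo_mixed_model(y, x, strains, A, chains = cfg$chains,
                                iters = cfg$iters, warmup = cfg$warmup,
                                seed = child_seed(cfg$seed, 60L))
  jsonlite::write_json(
    list(beta_mean = post$beta_mean, ci_low = post$ci_low,
         ci_high = post$ci_high, bayes_r2 = post$bayes_r2, p_d = post$p_d,
         rhat_max = post$rhat_max, n_draws = post$n_draws, n_obs = length(y)),
    file.path(out, "posterior.json"), auto_unbox = TRUE, digits = NA)
  list(posterior = post,
       summary = list(beta = post$beta_mean, p_d = post$p_d,
                      rhat_max = post$rhat_max, n_obs = length(y)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input simulation (optional), the hatch-count mixed
#' model with contrasts and effect sizes, development-time permutation
#' analyses, density and transcript linear models, within-strain
#' concordance, and the phylogenetic regression. Stage outputs are written
#' under `out_dir`; a machine-readable `summary.json` and a plain-text
#' `pipeline.log` summarize the run. Any stage failure aborts with an error
#' naming the stage.
#'
#' @param config A `"ci_pipeline_config"` (see [pipeline_config()]) or a
#'   path to a YAML file.
#' @return Invisibly, a list with per-stage results and the summary.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  stopifnot(inherits(cfg, "ci_pipeline_config"))
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- character()

  if (cfg$simulate) {
    if (is.null(cfg$strains) && is.null(cfg$temperatures)) {
      design <- default_design(cfg$replicates_per_cell)
    } else {
      full <- default_design(cfg$replicates_per_cell)
      s <- cfg$strains %||% full$strains
      tp <- cfg$temperatures %||% full$temperatures
      all_drops <- data.frame(strain = c("wTei", "wTri", "wTri"),
                              temperature = c(18, 18, 20))
      drops <- all_drops[all_drops$strain %in% s &
                         all_drops$temperature %in% tp, , drop = FALSE]
      design <- build_design(list(
        strains = s, temperatures = tp,
        cross_types = full$cross_types,
        replicates_per_cell = cfg$replicates_per_cell,
        drop_cells = if (nrow(drops)) drops else NULL))
    }
    params <- default_sim_params(design, seed = cfg$seed)
    paths <- write_simulated_inputs(file.path(out, "inputs"), design, params)
  } else {
    paths <- unlist(cfg$inputs)
  }
  # startup validation: every enabled stage's inputs must resolve
  need <- c(hatch = "crosses", devtime = "devtime", densities = "cq",
            expression = "ddpcr", phylo = "chronogram")
  for (stg in intersect(names(need), cfg$stages)) {
    if (!file.exists(paths[[need[[stg]]]]))
      stop_config("stage '", stg, "' input missing: ", paths[[need[[stg]]]])
  }

  state <- list(results = list())
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
    logf <<- c(logf, paste0("stage ", name, " completed in ", dt, "s"))
    res
  }

  if ("hatch" %in% cfg$stages)
    state$results$hatch <- run_stage("hatch", function()
      stage_hatch(cfg, paths, out))
  if ("devtime" %in% cfg$stages)
    state$results$devtime <- run_stage("devtime", function()
      stage_devtime(cfg, paths, out))
  if ("densities" %in% cfg$stages)
    state$results$densities <- run_stage("densities", function()
      stage_densities(cfg, paths, out))
  if ("expression" %in% cfg$stages)
    state$results$expression <- run_stage("expression", function()
      stage_expression(cfg, paths, out))
  if ("concordance" %in% cfg$stages)
    state$results$concordance <- run_stage("concordance", function()
      stage_concordance(cfg, state, out))
  if ("phylo" %in% cfg$stages)
    state$results$phylo <- run_stage("phylo", function()
      stage_phylo(cfg, paths, state, out))

  summary <- lapply(state$results, function(r) r$summary)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(logf, file.path(out, "pipeline.log"))
  invisible(c(state$results, list(summary = summary)))
}
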