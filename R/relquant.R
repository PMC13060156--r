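#' Delta-Cq fold-change between a target and a reference assay
#'
#' Triplicate Cq values are aggregated by arithmetic mean;
#' `DeltaCq = mean(cq_target) - mean(cq_reference)` and the relative
#' abundance is `2^-DeltaCq`. Undetermined wells enter as `NA`; a triplet is
#' usable while at least one well amplified. Optionally, a triplicate whose
#' spread exceeds `outlier_spread` cycles has its farthest-from-median well
#' dropped before averaging (off by default).
#'
#' @param cq_target,cq_reference Numeric vectors (typically length 3) of Cq
#'   values; `NA` marks undetermined wells.
#' @param drop_outlier Apply the max-spread triplicate rule (default FALSE).
#' @param outlier_spread Spread threshold in cycles (default 1).
#' @return A list with `delta_cq`, `fold` (`2^-delta_cq`), `log2_fold`
#'   (`-delta_cq`), and `ok`. If every well of either triplet is
#'   undetermined, `ok` is FALSE and the numeric fields are `NA`.
#' @examples
#' cq_to_fold(c(20.1, 20.0, 19.9), c(23.0, 23.1, 22.9))  # ~8-fold
#' @export
cq_to_fold <- function(cq_target, cq_reference, drop_outlier = FALSE,
                       outlier_spread = 1) {
  clean <- function(x) {
    x <- x[!is.na(x)]
    if (drop_outlier && length(x) >= 3 &&
        diff(range(x)) > outlier_spread) {
      x <- x[-which.max(abs(x - median(x)))]
    }
    x
  }
  tg <- clean(cq_target)
  rf <- clean(cq_reference)
  if (length(tg) == 0 || length(rf) == 0)
    return(list(delta_cq = NA_real_, fold = NA_real_,
                log2_fold = NA_real_, ok = FALSE))
  d <- mean(tg) - mean(rf)
  list(delta_cq = d, fold = 2^(-d), log2_fold = -d, ok = TRUE)
}

#' Total Wovirus density across variants
#'
#' Strains can carry several divergent prophage variants, each quantified
#' by its own assay. Total density is the arithmetic sum of per-variant
#' fold-changes, computed before any log transform.
#'
#' @param per_variant_folds Positive per-variant fold-changes.
#' @return Their sum, or `NA` with a warning for an empty input.
#' @export
sum_wovirus_variants <- function(per_variant_folds) {
  if (length(per_variant_folds) == 0) {
    warning("no detected variants; total Wovirus density is missing")
    return(NA_real_)
  }
  if (any(per_variant_folds <= 0)) stop("fold-changes must be positive")
  sum(per_variant_folds)
}

#' Spike-in-normalized transcript abundance
#'
#' ddPCR target concentration divided by the spike-in concentration,
#' normalizing for RNA purification and processing efficiency.
#'
#' @param conc_target Target concentration (copies/uL, >= 0).
#' @param conc_spike Spike-in concentration (copies/uL, > 0).
#' @return The ratio; a zero target returns 0 with a warning (it cannot be
#'   log2-transformed and is treated as missing downstream).
#' @export
spikein_abundance <- function(conc_target, conc_spike) {
  if (any(conc_spike <= 0)) stop("spike-in concentration must be positive")
  if (any(conc_target < 0)) stop("target concentration must be nonnegative")
  if (any(conc_target == 0))
    warning("zero target concentration; excluded from log-scale models")
  conc_target / conc_spike
}

#' Compute per-sample density metrics from a Cq table
#'
#' Aggregates a long Cq table (schema of [simulate_cq()]) into one row per
#' sample and metric: Wolbachia density per host (`ftsZ` vs the host
#' reference), Wovirus density per Wolbachia (serine-recombinase variants
#' vs `ftsZ`, summed across variants), and Wovirus density per host.
#' Samples whose required triplets are entirely undetermined are dropped
#' with a message.
#'
#' @param cq_table Data.frame with columns `sample_id`, `strain`,
#'   `temperature_c`, `target`, `cq1`, `cq2`, `cq3`.
#' @return A data.frame (`sample_id`, `strain`, `temperature_c`, `metric`,
#'   `fold`, `log2_fold`).
#' @export
densities_from_cq <- function(cq_table) {
  need <- c("sample_id", "strain", "temperature_c", "target",
            "cq1", "cq2", "cq3")
  stopifnot(all(need %in% names(cq_table)))
  out <- list()
  for (sid in unique(cq_table$sample_id)) {
    sub <- cq_table[cq_table$sample_id == sid, , drop = FALSE]
    trip <- function(tgt) {
      r <- sub[sub$target == tgt, c("cq1", "cq2", "cq3"), drop = FALSE]
      if (nrow(r) == 0) NULL else as.numeric(r[1, ])
    }
    host <- trip("host_reference")
    ftsz <- trip("ftsZ")
    if (is.null(host) || is.null(ftsz)) next
    w <- cq_to_fold(ftsz, host)
    add <- function(metric, fold) {
      out[[length(out) + 1]] <<- data.frame(
        sample_id = sid, strain = sub$strain[1],
        temperature_c = sub$temperature_c[1], metric = metric,
        fold = fold, log2_fold = log2(fold), stringsAsFactors = FALSE)
    }
    if (w$ok) add("wolbachia_per_host", w$fold)
    else message("sample ", sid, " excluded: undetermined triplet")
    variants <- setdiff(unique(sub$target), c("host_reference", "ftsZ"))
    if (length(variants)) {
      folds <- vapply(variants, function(v) {
        r <- cq_to_fold(trip(v), ftsz)
        if (r$ok) r$fold else NA_real_
      }, 1.0)
      folds <- folds[!is.na(folds)]
      if (length(folds)) {
        tot <- sum_wovirus_variants(folds)
        add("wovirus_per_wolbachia", tot)
        if (w$ok) add("wovirus_per_host", tot * w$fold)
      }
    }
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
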