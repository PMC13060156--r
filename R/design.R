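#' Build a validated experimental design
#'
#' A design records which strain-by-temperature cells were actually reared,
#' which cross types were performed in each, and the target replication.
#' Cells can be dropped (e.g. hosts that cannot be reared at a temperature)
#' via `drop_cells`.
#'
#' @param config A list with elements `strains` (character), `temperatures`
#'   (numeric, degrees C), `cross_types` (subset of `"compatible"`, `"ci"`,
#'   `"rescue"`), `replicates_per_cell` (positive integer, default 15) and
#'   optionally `drop_cells`, a data.frame with columns `strain` and
#'   `temperature` naming strain-temperature cells that were not reared.
#' @return An object of class `"ci_design"`: a list with `strains`,
#'   `temperatures`, `cross_types`, `replicates_per_cell` and `cells`
#'   (a data.frame of available strain-temperature pairs).
#' @examples
#' d <- build_design(list(strains = c("wA", "wB"), temperatures = c(18, 23),
#'                        cross_types = c("compatible", "ci")))
#' nrow(expand_cells(d))  # 8 strain x temperature x cross cells
#' @export
build_design <- function(config) {
  strains <- config$strains
  temps <- config$temperatures
  crosses <- config$cross_types %||% c("compatible", "ci", "rescue")
  reps <- config$replicates_per_cell %||% 15L
  if (length(strains) < 1) stop_config("at least one strain is required")
  if (length(temps) < 1) stop_config("at least one temperature is required")
  if (length(crosses) < 1) stop_config("at least one cross type is required")
  if (anyDuplicated(strains)) stop_config("duplicate strain labels")
  if (anyDuplicated(temps)) stop_config("duplicate temperatures")
  if (anyDuplicated(crosses)) stop_config("duplicate cross types")
  bad <- setdiff(crosses, c("compatible", "ci", "rescue"))
  if (length(bad))
    stop_config("unknown cross type(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(reps) || reps < 1)
    stop_config("replicates_per_cell must be >= 1")

  cells <- expand.grid(strain = strains, temperature = temps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  drop <- config$drop_cells
  if (!is.null(drop) && nrow(drop)) {
    key <- paste(cells$strain, cells$temperature)
    dkey <- paste(drop$strain, drop$temperature)
    missing_drop <- setdiff(dkey, key)
    if (length(missing_drop))
      stop_config("drop_cells not in design: ",
                  paste(missing_drop, collapse = "; "))
    cells <- cells[!key %in% dkey, , drop = FALSE]
  }
  if (nrow(cells) == 0) stop_config("all cells dropped; empty design")
  rownames(cells) <- NULL

  structure(list(strains = strains, temperatures = temps,
                 cross_types = crosses,
                 replicates_per_cell = as.integer(reps),
                 cells = cells),
            class = "ci_design")
}

#' Expand a design to strain x temperature x cross cells
#'
#' @param design A `"ci_design"` object.
#' @return A data.frame with columns `strain`, `temperature`, `cross_type`,
#'   one row per available analysis cell.
#' @export
expand_cells <- function(design) {
  stopifnot(inherits(design, "ci_design"))
  out <- merge(design$cells,
               data.frame(cross_type = design$cross_types,
                          stringsAsFactors = FALSE))
  out <- out[order(out$strain, out$temperature, out$cross_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("strain", "temperature", "cross_type")]
}

#' @export
print.ci_design <- function(x, ...) {
  cat("CI experimental design:", length(x$strains), "strain(s) x",
      length(x$temperatures), "temperature(s) x",
      length(x$cross_types), "cross type(s);",
      nrow(x$cells), "reared strain-temperature cells,",
      x$replicates_per_cell, "replicates per cell\n")
  invisible(x)
}

cell_key <- function(strain, temperature, cross = NULL) {
  if (is.null(cross)) paste(strain, format(temperature, trim = TRUE), sep = "|")
  else paste(strain, format(temperature, trim = TRUE), cross, sep = "|")
}

#' The default eight-strain cross design
#'
#' Eight Wolbachia-Drosophila systems reared at up to four temperatures
#' (18, 20, 23, 26 degrees C) with three cross types. The wTei host could
#' not be reared at 18 degrees C and the wTri host only at 23 and 26, so
#' those strain-temperature cells are absent.
#'
#' @param replicates_per_cell Egg-lay replicates per strain x temperature x
#'   cross cell (default 15, giving about 1300 crosses overall).
#' @return A `"ci_design"` object.
#' @export
default_design <- function(replicates_per_cell = 15L) {
  build_design(list(
    strains = c("wMel", "wTei", "wSeg", "wCha", "wBic", "wRi", "wTri", "wHa"),
    temperatures = c(18, 20, 23, 26),
    cross_types = c("compatible", "ci", "rescue"),
    replicates_per_cell = replicates_per_cell,
    drop_cells = data.frame(
      strain = c("wTei", "wTri", "wTri"),
      temperature = c(18, 18, 20))
  ))
}
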