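#' Perturbation specification
#'
#' In-silico analogues of the embryo manipulations: global AP
#' stretch/compression, posterior-graded stretch/compression, pPSM cell
#' deletion, and a change of progenitor-influx rate.  Strain perturbations
#' move cell positions only; deletion changes cell count only.  All apply
#' instantaneously between two iterations of [run_simulation()].
#'
#' @param kind one of `"GLOBAL_STRAIN"`, `"GRADED_STRAIN"`, `"DELETE_PPSM"`,
#'   `"SET_INFLUX"`.
#' @param strain signed total AP strain (negative = compression); the
#'   reference manipulations reach +/-10-15% total strain.
#' @param affected_fraction fraction of cells, counted from the posterior,
#'   displaced by a graded strain (default 0.75: the posterior 75% of cells).
#' @param decay_length AP length constant of the exponential displacement
#'   profile; `NULL` for the default, 1/3 of the affected zone's AP extent.
#' @param deletion_fraction fraction of pPSM cells removed by
#'   `DELETE_PPSM`.
#' @param influx_rate new influx rate installed by `SET_INFLUX`.
#' @param apply_at_iteration iteration after which the perturbation is
#'   applied (default 1000).
#' @param magnitude_parameter bookkeeping scalar recording the strength
#'   setting of the strong pull/compression conditions (value 80 in the
#'   reference runs); stored and reported, the physical `strain` remains the
#'   controlling input.
#' @return Object of class `perturbation_spec`.
#' @export
perturbation <- function(kind = c("GLOBAL_STRAIN", "GRADED_STRAIN",
                                  "DELETE_PPSM", "SET_INFLUX"),
                         strain = 0, affected_fraction = 0.75,
                         decay_length = NULL, deletion_fraction = 0,
                         influx_rate = NULL, apply_at_iteration = 1000L,
                         magnitude_parameter = NA_real_) {
  kind <- match.arg(kind)
  if (kind %in% c("GLOBAL_STRAIN", "GRADED_STRAIN"))
    stopifnot(abs(strain) > 0, abs(strain) <= 0.5)
  stopifnot(affected_fraction > 0, affected_fraction <= 1,
            deletion_fraction >= 0, deletion_fraction <= 1)
  if (!is.null(decay_length)) stopifnot(decay_length > 0)
  if (kind == "SET_INFLUX") stopifnot(!is.null(influx_rate), influx_rate >= 0)
  structure(list(kind = kind, strain = strain,
                 affected_fraction = affected_fraction,
                 decay_length = decay_length,
                 deletion_fraction = deletion_fraction,
                 influx_rate = influx_rate,
                 apply_at_iteration = as.integer(apply_at_iteration),
                 magnitude_parameter = magnitude_parameter),
            class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat("Perturbation: ", x$kind, sep = "")
  if (x$kind %in% c("GLOBAL_STRAIN", "GRADED_STRAIN"))
    cat(", strain ", x$strain, sep = "")
  if (x$kind == "GRADED_STRAIN")
    cat(", posterior fraction ", x$affected_fraction, sep = "")
  if (x$kind == "DELETE_PPSM")
    cat(", deletion fraction ", x$deletion_fraction, sep = "")
  if (x$kind == "SET_INFLUX")
    cat(", influx rate ", x$influx_rate, sep = "")
  cat(", at iteration ", x$apply_at_iteration, "\n", sep = "")
  invisible(x)
}

# dispatcher used by run_simulation
apply_perturbation <- function(cells, spec, geometry = NULL) {
  switch(spec$kind,
    GLOBAL_STRAIN = apply_global_strain(cells, spec$strain),
    GRADED_STRAIN = apply_graded_strain(cells, spec$strain,
                                        spec$affected_fraction,
                                        spec$decay_length),
    DELETE_PPSM = delete_ppsm_cells(cells, spec$deletion_fraction),
    SET_INFLUX = cells)
}

#' Global AP strain
#'
#' Rescales every AP coordinate by `(1 + strain)` about the anterior wall
#' (AP = `anterior`); ML/DV coordinates are unchanged.  The whole simulated
#' field is compacted (negative strain) or stretched (positive) equally.
#'
#' @param x construct or cells data.frame.
#' @param strain signed fraction.
#' @param anterior anterior wall coordinate (default 0).
#' @return Cells data.frame (or construct, matching the input class).
#' @export
apply_global_strain <- function(x, strain, anterior = 0) {
  cells <- as_cells(x)
  if (nrow(cells) == 0) stop("empty state")
  cells$x <- anterior + (cells$x - anterior) * (1 + strain)
  if (inherits(x, "tissue_construct")) { x$cells <- cells; x } else cells
}

#' Posterior-graded (exponential) AP strain
#'
#' Displaces the posterior `affected_fraction` of cells (by AP rank) along
#' AP by `delta(a) = A * exp((a - a_max) / decay_length)`, so posterior cells
#' are displaced more, with amplitude `A` chosen so the total AP strain of
#' the whole field equals `strain`.  The anterior cells are unmoved and the
#' AP order of cells is preserved (the displacement map is monotone for the
#' strains in range).
#'
#' @inheritParams apply_global_strain
#' @param affected_fraction posterior fraction of cells displaced
#'   (default 0.75).
#' @param decay_length exponential length constant; `NULL` = 1/3 of the
#'   affected zone's AP extent.
#' @return Cells data.frame (or construct, matching the input class).
#' @export
apply_graded_strain <- function(x, strain, affected_fraction = 0.75,
                                decay_length = NULL) {
  cells <- as_cells(x)
  if (nrow(cells) == 0) stop("empty state")
  if (!is.null(decay_length) && decay_length <= 0)
    stop("decay_length must be positive")
  n <- nrow(cells)
  n_aff <- ceiling(affected_fraction * n)
  ord <- order(cells$x, cells$id)
  affected <- ord[(n - n_aff + 1):n]
  a <- cells$x[affected]
  a_max <- max(a)
  extent <- a_max - min(cells$x)
  if (is.null(decay_length)) {
    zone <- a_max - min(a)
    decay_length <- max(zone / 3, 1e-8)
  }
  A <- strain * extent
  cells$x[affected] <- a + A * exp((a - a_max) / decay_length)
  if (inherits(x, "tissue_construct")) { x$cells <- cells; x } else cells
}

#' Delete a fraction of pPSM cells
#'
#' Removes a uniformly sampled fraction of the PSM cells inside the pPSM
#' region — the posterior `ppsm_extent` AP units up to the posterior-most
#' axial cell.  Sampling is without replacement and deterministic under the
#' session RNG seed.
#'
#' @inheritParams apply_global_strain
#' @param deletion_fraction fraction in \[0, 1\].
#' @param ppsm_extent AP depth of the pPSM region (default 5 units).
#' @return Cells data.frame (or construct, matching the input class).
#' @export
delete_ppsm_cells <- function(x, deletion_fraction, ppsm_extent = 5) {
  cells <- as_cells(x)
  stopifnot(deletion_fraction >= 0, deletion_fraction <= 1)
  idx <- ppsm_indices(cells, ppsm_extent)
  if (length(idx) == 0) stop("pPSM region contains no PSM cells")
  k <- round(deletion_fraction * length(idx))
  if (k > 0) {
    drop <- sample(idx, k)
    cells <- cells[-drop, , drop = FALSE]
    rownames(cells) <- NULL
  }
  if (inherits(x, "tissue_construct")) { x$cells <- cells; x } else cells
}

# row indices of PSM cells in the pPSM band (posterior `extent` units up to
# the posterior-most axial cell)
ppsm_indices <- function(cells, extent = 5) {
  ax <- cells$x[cells$type == "AXIAL"]
  if (length(ax) == 0) stop("state has no AXIAL cells")
  ax_max <- max(ax)
  which(cells$type == "PSM" & cells$x <= ax_max & cells$x >= ax_max - extent)
}
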