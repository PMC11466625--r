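#' Axis length of a state
#'
#' Body-axis length measured by the mean AP position of the 4 posterior-most
#' axial cells, relative to the anterior wall.  Ties in AP coordinate are
#' broken by cell id.
#'
#' @param x construct, cells data.frame, or `axis_trajectory` (final state).
#' @param anterior anterior wall AP coordinate (default 0).
#' @return Length in model length units.
#' @export
axis_length <- function(x, anterior = 0) {
  if (inherits(x, "axis_trajectory")) x <- x$final
  cells <- as_cells(x)
  ax <- cells[cells$type == "AXIAL", ]
  if (nrow(ax) < 4) stop("axis_length requires at least 4 AXIAL cells")
  ord <- order(-ax$x, ax$id)
  mean(ax$x[ord[1:4]]) - anterior
}

# axis length at a given snapshot index
snapshot_axis_length <- function(trajectory, i) {
  axis_length(get_snapshot(trajectory, i))
}

#' Elongation extent of a perturbed run
#'
#' Ratio between the final axial length and the length immediately after the
#' perturbation (first post-perturbation snapshot); for unperturbed runs, the
#' initial snapshot is the reference.
#'
#' @param trajectory an `axis_trajectory`.
#' @param from_iteration optional reference iteration for unperturbed
#'   (control) runs: the first snapshot at or after it is used as the
#'   denominator, making control extents comparable with perturbed groups.
#' @return Ratio (dimensionless).
#' @export
elongation_extent <- function(trajectory, from_iteration = NULL) {
  i0 <- trajectory$post_perturbation_snapshot
  if (is.na(i0)) {
    i0 <- if (is.null(from_iteration)) 1L
          else which(snapshot_iters(trajectory) >= from_iteration)[1]
    if (is.na(i0)) stop("no snapshot at or after `from_iteration`")
  }
  l0 <- snapshot_axis_length(trajectory, i0)
  if (!is.finite(l0) || l0 == 0) stop("zero initial axis length")
  snapshot_axis_length(trajectory, n_snapshots(trajectory)) / l0
}

new_timeseries <- function(quantity, bin_axis, bin_width, bin, mean, sd, n) {
  out <- data.frame(quantity = quantity, bin = bin, mean = mean, sd = sd,
                    n = n)
  attr(out, "bin_axis") <- bin_axis
  attr(out, "bin_width") <- bin_width
  out
}

#' PSM cell-density profile versus distance to the axis end
#'
#' Counts PSM cells in square grids of side `grid_size` and aggregates the
#' per-grid counts into bands of distance to the posterior axis end (the
#' posterior-most axial cell).  Bands within `ppsm_extent` of the axis end
#' are labeled pPSM, the rest aPSM.
#'
#' @param x construct, cells data.frame, or trajectory (final state).
#' @param grid_size grid side in length units (default 1).
#' @param ppsm_extent AP depth of the pPSM label (default 5 units).
#' @return Data.frame `quantity`, `bin` (band anterior distance), `mean`,
#'   `sd`, `n` (grids per band), `region`.
#' @export
density_profile <- function(x, grid_size = 1, ppsm_extent = 5) {
  if (inherits(x, "axis_trajectory")) x <- x$final
  cells <- as_cells(x)
  ax <- cells$x[cells$type == "AXIAL"]
  if (length(ax) == 0) stop("state has no AXIAL cells")
  axis_end <- max(ax)
  psm <- cells[cells$type == "PSM" & cells$x <= axis_end, ]
  dist <- axis_end - psm$x
  band <- floor(dist / grid_size)
  ml <- floor(psm$y / grid_size)
  if (nrow(psm) == 0) {
    return(new_timeseries("density", "distance_to_axis_end", grid_size,
                          numeric(0), numeric(0), numeric(0), integer(0)))
  }
  counts <- table(band, ml)
  bands <- as.numeric(rownames(counts))
  m <- apply(counts, 1, mean)
  s <- apply(counts, 1, sd)
  out <- new_timeseries("density", "distance_to_axis_end", grid_size,
                        bands * grid_size, as.numeric(m), as.numeric(s),
                        as.integer(ncol(counts)))
  out$region <- ifelse(out$bin < ppsm_extent, "pPSM", "aPSM")
  out
}

#' Boundary pressure along the AP axis
#'
#' Sums the wall-collision impulse magnitudes of PSM cells into AP bins
#' (1 length unit wide by default, the starting field being 15 units),
#' normalized per iteration.  Impulses are tallied during the run (see
#' [run_simulation()]).
#'
#' @param trajectory an `axis_trajectory`.
#' @param from,to iteration window (defaults: after the perturbation if any,
#'   else the whole run).
#' @param max_bin drop trailing all-zero AP bins beyond this (default: keep
#'   all bins that ever saw a collision).
#' @return Data.frame `quantity`, `bin` (AP bin lower edge), `mean`
#'   (impulse per iteration), `sd` (across tally chunks), `n` (chunks).
#' @export
boundary_pressure <- function(trajectory, from = NULL, to = NULL,
                              max_bin = NULL) {
  imp <- trajectory$impulse
  if (is.null(imp) || sum(imp) == 0)
    warning("collision log is empty; returning zero pressure")
  re <- trajectory$record_every
  n_chunks <- nrow(imp)
  chunk_start <- (seq_len(n_chunks) - 1) * re
  if (is.null(from))
    from <- if (!is.na(trajectory$perturbation_iteration))
      trajectory$perturbation_iteration else 0
  if (is.null(to)) to <- trajectory$n_iterations
  keep <- chunk_start >= from & chunk_start < to
  sub <- imp[keep, , drop = FALSE]
  per_iter <- sub / re
  m <- colMeans(per_iter)
  s <- apply(per_iter, 2, sd)
  bins <- (seq_len(ncol(imp)) - 1) * trajectory$ap_bin_width
  if (is.null(max_bin)) {
    nz <- which(colSums(imp) > 0)
    max_bin <- if (length(nz)) bins[max(nz)] else bins[15]
  }
  keep_b <- bins <= max_bin
  new_timeseries("boundary_pressure", "AP_unit", trajectory$ap_bin_width,
                 bins[keep_b], m[keep_b], s[keep_b], sum(keep))
}

bin_series <- function(values, quantity, bin_width = 200, from = 0) {
  it <- seq_along(values)
  keep <- it > from
  v <- values[keep]; it <- it[keep]
  bin <- floor((it - from - 1) / bin_width)
  m <- tapply(v, bin, mean)
  s <- tapply(v, bin, sd)
  n <- tapply(v, bin, length)
  new_timeseries(quantity, "iteration", bin_width,
                 from + as.numeric(names(m)) * bin_width,
                 as.numeric(m), as.numeric(s), as.integer(n))
}

#' Axial pushing force over time
#'
#' The summed A-to-P interaction force on the 4 posterior-most axial cells
#' (the same cell set as [axis_length()]), recorded every iteration during
#' the run and binned (200 iterations by default, counted from the
#' perturbation when there is one).
#'
#' @param trajectory an `axis_trajectory`.
#' @param bin_width iterations per bin.
#' @param from first iteration of the binning (default: the perturbation
#'   iteration, else 0).
#' @return Data.frame `quantity`, `bin`, `mean`, `sd`, `n`.
#' @export
axial_push_force <- function(trajectory, bin_width = 200, from = NULL) {
  f <- trajectory$force_series
  if (all(is.na(f))) stop("force series not recorded; re-run the simulation")
  if (is.null(from))
    from <- if (!is.na(trajectory$perturbation_iteration))
      trajectory$perturbation_iteration else 0
  bin_series(f, "axial_push_force", bin_width, from)
}

#' Progenitor-domain lateral flux
#'
#' For each pair of consecutive snapshots, identifies the PD cells (via
#' [pd_mask()] on the earlier snapshot), computes each cell's absolute ML
#' speed `|delta ML| / delta iterations`, and averages per bin of
#' `bin_width` iterations.  Bins without any PD cell are `NA`, not zero.
#'
#' @param trajectory an `axis_trajectory` with >= 2 snapshots.
#' @param bin_width iterations per bin (default 200).
#' @param halfwidth PD midline half-width.
#' @param from first iteration of the binning (default: the perturbation
#'   iteration, else 0).
#' @param signed if `TRUE`, report the signed medial-to-lateral speed
#'   (positive = away from the midline) instead of the absolute speed.
#' @return Data.frame `quantity`, `bin`, `mean`, `sd`, `n` (cell
#'   observations per bin).
#' @export
pd_lateral_flux <- function(trajectory, bin_width = 200, halfwidth = 1,
                            from = NULL, signed = FALSE) {
  ns <- n_snapshots(trajectory)
  if (ns < 2) stop("pd_lateral_flux requires at least 2 snapshots")
  if (is.null(from))
    from <- if (!is.na(trajectory$perturbation_iteration))
      trajectory$perturbation_iteration else 0
  iters <- snapshot_iters(trajectory)
  speeds <- numeric(0)
  at_iter <- numeric(0)
  for (k in seq_len(ns - 1)) {
    dt_it <- iters[k + 1] - iters[k]
    if (dt_it <= 0) next
    a <- get_snapshot(trajectory, k)
    b <- get_snapshot(trajectory, k + 1)
    ids <- intersect(pd_mask(a, halfwidth), b$id)
    if (length(ids) == 0) next
    ya <- a$y[match(ids, a$id)]
    yb <- b$y[match(ids, b$id)]
    sp <- if (signed) (abs(yb) - abs(ya)) / dt_it else abs(yb - ya) / dt_it
    speeds <- c(speeds, sp)
    at_iter <- c(at_iter, rep(iters[k], length(sp)))
  }
  keep <- at_iter >= from
  speeds <- speeds[keep]; at_iter <- at_iter[keep]
  if (length(speeds) == 0)
    return(new_timeseries("pd_lateral_flux", "iteration", bin_width,
                          numeric(0), numeric(0), numeric(0), integer(0)))
  bin <- floor((at_iter - from) / bin_width)
  m <- tapply(speeds, bin, mean)
  s <- tapply(speeds, bin, sd)
  n <- tapply(speeds, bin, length)
  new_timeseries("pd_lateral_flux", "iteration", bin_width,
                 from + as.numeric(names(m)) * bin_width,
                 as.numeric(m), as.numeric(s), as.integer(n))
}

#' Classify the collective-movement regime of a run
#'
#' Decomposes each PSM/axial cell's net displacement between two snapshots
#' into a convergence component (decrease of |ML|, movement toward the
#' midline) and an elongation component (posterior AP movement), sums the
#' component magnitudes over cells, and labels the run by the dominant
#' component.  The continuous elongation/convergence ratio is returned for
#' transition detection; a run with zero net displacement everywhere is
#' `UNDETERMINED`.
#'
#' @param trajectory an `axis_trajectory` (or a list of two cells
#'   data.frames).
#' @param from,to snapshot indices (defaults: first and last).
#' @return List with `label` (`"CONVERGENCE"`, `"ELONGATION"` or
#'   `"UNDETERMINED"`), `ratio` (elongation / convergence totals),
#'   `elongation`, `convergence` (summed magnitudes), and `cells` (per-cell
#'   components and dominant-component label).
#' @export
classify_regime <- function(trajectory, from = 1L, to = NULL) {
  if (inherits(trajectory, "axis_trajectory")) {
    if (is.null(to)) to <- n_snapshots(trajectory)
    if (to <= from) stop("trajectory must span at least 2 snapshots")
    a <- get_snapshot(trajectory, from)
    b <- get_snapshot(trajectory, to)
  } else {
    a <- trajectory[[1]]; b <- trajectory[[2]]
  }
  ids <- intersect(a$id[a$type %in% c("PSM", "AXIAL")], b$id)
  ia <- match(ids, a$id); ib <- match(ids, b$id)
  elong <- pmax(b$x[ib] - a$x[ia], 0)
  conv <- pmax(abs(a$y[ia]) - abs(b$y[ib]), 0)
  E <- sum(elong); C <- sum(conv)
  label <- if (E == 0 && C == 0) "UNDETERMINED"
           else if (E > C) "ELONGATION" else "CONVERGENCE"
  cells <- data.frame(id = ids, x = a$x[ia], y = a$y[ia],
                      elongation = elong, convergence = conv,
                      dominant = ifelse(elong == conv, "TIE",
                                 ifelse(elong > conv, "ELONGATION",
                                        "CONVERGENCE")))
  list(label = label, ratio = if (C > 0) E / C else Inf,
       elongation = E, convergence = C, cells = cells)
}

#' Average replicate readout tables
#'
#' Aligns a list of per-replicate tables (same `quantity`, same binning) on
#' their bins and returns the across-replicate mean and SD of the per-bin
#' means, the usual mean +/- SD replicate aggregation of the simulated
#' readouts.
#'
#' @param tables list of data.frames from the readout functions.
#' @return Data.frame `quantity`, `bin`, `mean`, `sd`, `n` (replicates per
#'   bin).
#' @export
aggregate_replicates <- function(tables) {
  stopifnot(length(tables) >= 1)
  all_bins <- sort(unique(unlist(lapply(tables, function(t) t$bin))))
  vals <- sapply(tables, function(t) t$mean[match(all_bins, t$bin)])
  vals <- matrix(vals, nrow = length(all_bins))
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1, sd, na.rm = TRUE)
  n <- rowSums(!is.na(vals))
  new_timeseries(tables[[1]]$quantity[1], attr(tables[[1]], "bin_axis"),
                 attr(tables[[1]], "bin_width"), all_bins, m, s,
                 as.integer(n))
}
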