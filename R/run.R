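#' Run a simulation
#'
#' Integrates the overdamped model from a [build_construct()] initial
#' condition for `n_iterations` iterations, with optional progenitor influx
#' and an optional perturbation applied instantaneously between iterations.
#' Snapshots of all cell positions, the per-iteration axis length and axial
#' pushing force, and the wall-collision impulse tally are recorded.  Runs
#' are fully reproducible: identical `(construct, params, seed, ...)` give
#' bit-identical trajectories.
#'
#' The axis length series is the mean AP coordinate of the 4 posterior-most
#' axial cells (the anterior wall sits at AP = 0).  The force series is the
#' summed AP component of the cell-cell interaction forces on that same
#' 4-cell set (motility and wall terms excluded; in the overdamped model
#' these interaction terms are velocity contributions, reported as forces).
#'
#' @param construct a [build_construct()] result (or a state from a previous
#'   run via [as_construct()]).
#' @param params a [mechanics_params()].
#' @param n_iterations number of iterations (>= 1).
#' @param influx_rate expected new PSM cells per iteration (Poisson); 0
#'   reproduces the no-influx condition.
#' @param perturbation optional [perturbation()]; applied between iterations
#'   `apply_at_iteration` and `apply_at_iteration + 1`.
#' @param record_every snapshot / tally-chunk cadence in iterations.
#' @param seed integer seed controlling all randomness of the run.
#' @param neighbor_search `"bins"` (uniform spatial binning, default) or
#'   `"brute"` (all-pairs; for verification).
#' @param pd_halfwidth,pd_depth progenitor-domain geometry used for influx
#'   insertion: new cells appear in the posterior half of the AP window
#'   `(tip, tip + pd_depth)` (anchored at the posterior-cap front when a
#'   cap is present) within `|ML| <= pd_halfwidth`.  The default half-width
#'   spans the posterior band up to half a unit short of the lateral walls:
#'   progenitors enter the posterior PSM across the whole mediolateral
#'   extent of the domain.  Readout masks ([pd_mask()],
#'   [pd_lateral_flux()]) keep their own, narrower midline half-width.
#' @param influx_min_space minimum clearance of an influx birth position to
#'   existing cells, in units of the cell radius (default 1.3: births fill
#'   loose space rather than creating deep overlaps).
#' @param ap_bin_width,n_ap_bins AP binning of the wall-impulse tally.
#' @return An object of class `axis_trajectory`; see Details.  Elements
#'   include `snapshots` (list of `iter`/`id`/`type`/`pos`), `length_series`
#'   and `force_series` (per iteration), `impulse` (chunk x AP-bin matrix of
#'   summed PSM wall impulses), `final` (final cells data.frame),
#'   `post_perturbation_snapshot` (index, or NA).
#' @examples
#' tc <- build_construct(2, seed = 1)
#' tr <- run_simulation(tc, n_iterations = 50, record_every = 25, seed = 1)
#' axis_length(tr$final)
#' @export
run_simulation <- function(construct, params = mechanics_params(),
                           n_iterations, influx_rate = 0,
                           perturbation = NULL, record_every = 50L,
                           seed = 1L, neighbor_search = c("bins", "brute"),
                           pd_halfwidth = NULL, pd_depth = NULL,
                           influx_min_space = 1.3,
                           ap_bin_width = 1, n_ap_bins = 80L) {
  stopifnot(inherits(construct, "tissue_construct"), n_iterations >= 1,
            influx_rate >= 0, record_every >= 1)
  neighbor_search <- match.arg(neighbor_search)
  if (!is.null(perturbation) && !inherits(perturbation, "perturbation_spec"))
    stop("`perturbation` must be a perturbation() spec")
  set.seed(as.integer(seed))

  segs <- list()
  pert_at <- if (is.null(perturbation)) NA_integer_
             else as.integer(perturbation$apply_at_iteration)
  if (!is.null(perturbation) && pert_at >= 1 && pert_at < n_iterations) {
    segs <- list(c(0L, pert_at), c(pert_at, as.integer(n_iterations)))
  } else {
    segs <- list(c(0L, as.integer(n_iterations)))
    if (!is.null(perturbation))
      warning("perturbation iteration outside (0, n_iterations); not applied")
  }

  cells <- construct$cells
  geometry <- construct$geometry
  dim <- construct$dimension
  if (is.null(pd_halfwidth))
    pd_halfwidth <- geometry$axial_halfwidth + geometry$psm_width - 0.5
  if (is.null(pd_depth)) pd_depth <- geometry$pd_depth
  zlim <- if (dim == 3) c(0.5, geometry$dv_thickness - 0.5) else c(0, 0)
  rate <- influx_rate
  next_id <- max(cells$id) + 1L
  psm_like <- cells$type == "PSM"
  new_radius <- if (any(psm_like)) stats::median(cells$radius[psm_like])
                else stats::median(cells$radius)
  new_adh <- new_radius * 1.25

  snapshots <- list()
  length_series <- numeric(0)
  force_series <- numeric(0)
  impulse <- NULL
  added <- skipped <- clamped <- 0L
  post_idx <- NA_integer_

  for (s in seq_along(segs)) {
    it0 <- segs[[s]][1]; it1 <- segs[[s]][2]
    pos <- as.matrix(cells[, c("x", "y", if (dim == 3) "z")])
    res <- cpp_run(pos, type_code(cells$type), as.integer(cells$id),
                   cells$radius, cells$adhesion_distance,
                   params$repulsion, params$adhesion,
                   unname(params$motility), params$boundary_repulsion,
                   geometry$normals, unname(geometry$offsets),
                   params$dt, params$motility_persistence, params$step_clamp,
                   it1 - it0, it0, as.integer(record_every),
                   rate, pd_halfwidth, pd_depth, zlim[1], zlim[2],
                   influx_min_space * new_radius, new_radius, new_adh, next_id,
                   dim, neighbor_search == "bins",
                   ap_bin_width, as.integer(n_ap_bins))
    keep <- res$snapshots
    if (s > 1) {
      # the segment's initial snapshot is the first post-perturbation state
      post_idx <- length(snapshots) + 1L
    }
    snapshots <- c(snapshots, keep)
    length_series <- c(length_series, res$length_series)
    force_series <- c(force_series, res$force_series)
    impulse <- rbind(impulse, res$impulse)
    added <- added + res$n_added
    skipped <- skipped + res$n_skipped
    clamped <- clamped + res$n_clamped
    next_id <- res$next_id

    cells <- data.frame(id = res$id, type = type_name(res$type),
                        x = res$pos[, 1], y = res$pos[, 2])
    if (dim == 3) cells$z <- res$pos[, 3]
    cells$radius <- res$radius
    cells$adhesion_distance <- res$adh_dist

    if (s < length(segs)) {
      cells <- apply_perturbation(cells, perturbation, geometry)
      if (perturbation$kind == "SET_INFLUX") rate <- perturbation$influx_rate
    }
  }

  structure(list(
    snapshots = snapshots,
    length_series = length_series,
    force_series = force_series,
    impulse = impulse,
    record_every = as.integer(record_every),
    ap_bin_width = ap_bin_width,
    construct = construct, params = params,
    influx_rate = influx_rate, perturbation = perturbation,
    perturbation_iteration = pert_at,
    post_perturbation_snapshot = post_idx,
    n_iterations = as.integer(n_iterations),
    final = cells, dimension = dim, seed = as.integer(seed),
    n_added = added, n_skipped = skipped, n_clamped = clamped),
    class = "axis_trajectory")
}

#' Extract a snapshot as a cells data.frame
#'
#' @param trajectory an `axis_trajectory`.
#' @param i snapshot index (1 = initial state) or `"final"`.
#' @return Cells data.frame (radius/adhesion distance of influx cells use the
#'   PSM defaults).
#' @export
get_snapshot <- function(trajectory, i) {
  if (identical(i, "final")) return(trajectory$final)
  s <- trajectory$snapshots[[i]]
  d <- data.frame(id = s$id, type = type_name(s$type),
                  x = s$pos[, 1], y = s$pos[, 2])
  if (ncol(s$pos) == 3) d$z <- s$pos[, 3]
  d$radius <- 0.5
  mult <- c(AXIAL = 1.1, PSM = 1.25, POSTERIOR = 1.1)
  d$adhesion_distance <- d$radius * unname(mult[d$type])
  d
}

#' Number of recorded snapshots
#' @param trajectory an `axis_trajectory`.
#' @export
n_snapshots <- function(trajectory) length(trajectory$snapshots)

snapshot_iters <- function(trajectory)
  vapply(trajectory$snapshots, function(s) s$iter, integer(1))

#' Rebuild a construct from a trajectory's final state
#'
#' Allows a finished run to seed a follow-up [run_simulation()].
#' @param trajectory an `axis_trajectory`.
#' @return A `tissue_construct` whose cells are the final state.
#' @export
as_construct <- function(trajectory) {
  structure(list(cells = trajectory$final,
                 geometry = trajectory$construct$geometry,
                 dimension = trajectory$dimension,
                 counts = NULL, seed = trajectory$seed),
            class = "tissue_construct")
}

#' @export
print.axis_trajectory <- function(x, ...) {
  cat("Axis-elongation trajectory: ", x$n_iterations, " iterations, ",
      nrow(x$final), " final cells (", x$n_added, " added by influx), ",
      n_snapshots(x), " snapshots\n", sep = "")
  len <- x$length_series
  cat("  axis length ", round(len[1], 2), " -> ",
      round(len[length(len)], 2), " length units\n", sep = "")
  if (!is.na(x$perturbation_iteration))
    cat("  perturbation (", x$perturbation$kind, ") at iteration ",
        x$perturbation_iteration, "\n", sep = "")
  invisible(x)
}

#' @export
plot.axis_trajectory <- function(x, ...) {
  plot(seq_along(x$length_series), x$length_series, type = "l",
       xlab = "iteration", ylab = "axis length (length units)", ...)
  if (!is.na(x$perturbation_iteration))
    graphics::abline(v = x$perturbation_iteration, lty = 2, col = "red")
  invisible(x)
}
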