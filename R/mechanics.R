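#' Mechanical interaction parameters
#'
#' Bundles the per-type and per-type-pair coefficients of the overdamped
#' center-based model and the integration settings.  Homotypic coefficients
#' are placed on the diagonal of symmetric 3x3 type-pair matrices;
#' heterotypic entries default to the geometric mean of the homotypic values
#' unless overridden.  The PSM-AXIAL and PSM-POSTERIOR repulsions are
#' overridden by default to 50 and 35 — the midpoints of their explored
#' ranges — giving the tissue interfaces the strong repulsion that keeps
#' the passive tissues segregated from the motile PSM (with the geometric
#' mean, ~10, the tissues intermix and the axial column loses integrity).
#'
#' The defaults are the reference cell-type table of the model: relative
#' repulsion 10 for all three types; relative adhesion 2.5 (axial), 0.05
#' (PSM), 1 (posterior); directionless motility 1.2 for PSM and 0 for the
#' passive types; maximum adhesion distance 1.1x radius (axial, posterior)
#' and 1.25x radius (PSM).
#'
#' @param repulsion named homotypic repulsion coefficients.
#' @param adhesion named homotypic adhesion coefficients.
#' @param motility named motility magnitudes (length units per time unit).
#' @param adhesion_multiplier named maximum-adhesion-distance multipliers.
#' @param boundary_repulsion rigid-wall repulsion coefficient; the repulsion
#'   range is the cell radius.
#' @param dt integration step (time units per iteration).
#' @param motility_persistence iterations between redraws of each motile
#'   cell's direction (1 = a fresh uniform direction every iteration).
#' @param step_clamp maximum per-step displacement (length units), a
#'   safeguard for stiff transient contacts.
#' @param repulsion_pairs,adhesion_pairs optional named numeric vectors of
#'   heterotypic overrides, names like `"PSM-AXIAL"`.
#' @return Object of class `mechanics_params`.
#' @examples
#' p <- mechanics_params(repulsion_pairs = c("PSM-AXIAL" = 50))
#' p$repulsion
#' @export
mechanics_params <- function(repulsion = c(AXIAL = 10, PSM = 10, POSTERIOR = 10),
                             adhesion = c(AXIAL = 2.5, PSM = 0.05, POSTERIOR = 1),
                             motility = c(AXIAL = 0, PSM = 1.2, POSTERIOR = 0),
                             adhesion_multiplier = c(AXIAL = 1.1, PSM = 1.25,
                                                     POSTERIOR = 1.1),
                             boundary_repulsion = 10,
                             dt = 0.01, motility_persistence = 1L,
                             step_clamp = 0.3,
                             repulsion_pairs = c("PSM-AXIAL" = 50,
                                                 "PSM-POSTERIOR" = 35),
                             adhesion_pairs = NULL) {
  tn <- names(TISSUE_TYPES)
  stopifnot(all(tn %in% names(repulsion)), all(tn %in% names(adhesion)),
            all(tn %in% names(motility)), dt > 0, motility_persistence >= 1,
            all(repulsion >= 0), all(adhesion >= 0), boundary_repulsion >= 0)
  pair_matrix <- function(homo, overrides) {
    m <- sqrt(outer(homo[tn], homo[tn]))
    dimnames(m) <- list(tn, tn)
    for (nm in names(overrides)) {
      ab <- strsplit(nm, "-", fixed = TRUE)[[1]]
      if (length(ab) != 2 || !all(ab %in% tn))
        stop("bad pair override name: ", nm)
      m[ab[1], ab[2]] <- m[ab[2], ab[1]] <- overrides[[nm]]
    }
    m
  }
  structure(list(
    repulsion = pair_matrix(repulsion, repulsion_pairs),
    adhesion = pair_matrix(adhesion, adhesion_pairs),
    motility = motility[tn],
    adhesion_multiplier = adhesion_multiplier[tn],
    boundary_repulsion = boundary_repulsion,
    dt = dt, motility_persistence = as.integer(motility_persistence),
    step_clamp = step_clamp), class = "mechanics_params")
}

#' @export
print.mechanics_params <- function(x, ...) {
  cat("Mechanics parameters (overdamped center-based model)\n")
  cat("  repulsion:\n"); print(x$repulsion)
  cat("  adhesion:\n"); print(x$adhesion)
  cat("  motility: ", paste(names(x$motility), x$motility, sep = "=",
                            collapse = ", "), "\n")
  cat("  boundary repulsion ", x$boundary_repulsion,
      ", dt ", x$dt, ", persistence ", x$motility_persistence, "\n", sep = "")
  invisible(x)
}

cell_row <- function(cell) {
  # accept a 1-row data.frame or a list(position=, type=, radius=, ...)
  if (is.data.frame(cell)) {
    pos <- c(cell$x, cell$y, if (!is.null(cell$z)) cell$z)
    list(position = pos, type = cell$type, radius = cell$radius,
         adhesion_distance = cell$adhesion_distance)
  } else cell
}

#' Pairwise velocity contribution between two cells
#'
#' The velocity contribution of cell `j` on cell `i`: a quadratic-falloff
#' repulsion of magnitude `sqrt(c_r^i * c_r^j) * (1 - d/(R_i+R_j))^2` along
#' the `j -> i` direction when centers overlap (`d < R_i + R_j`), a
#' quadratic-falloff adhesion of magnitude
#' `sqrt(c_a^i * c_a^j) * (1 - d/(A_i+A_j))^2` along `i -> j` when
#' `R_i+R_j <= d < A_i+A_j` (A = maximum adhesion distance), and zero beyond
#' the adhesion range.  Heterotypic coefficients are read from the type-pair
#' matrices of `params`.  Coincident centers are separated along a random
#' unit direction (seed the RNG for reproducibility).
#'
#' This is the reference (readable) implementation; simulation runs evaluate
#' the same force law in compiled code.
#'
#' @param cell_i,cell_j cells: 1-row data.frames (as in a construct's
#'   `cells`) or lists with `position`, `type`, `radius`,
#'   `adhesion_distance`.
#' @param params a [mechanics_params()].
#' @return Velocity vector for cell `i`.
#' @examples
#' p <- mechanics_params()
#' a <- list(position = c(0, 0), type = "PSM", radius = 0.5,
#'           adhesion_distance = 0.625)
#' b <- list(position = c(0.8, 0), type = "PSM", radius = 0.5,
#'           adhesion_distance = 0.625)
#' pair_velocity(a, b, p)   # repulsion 10 * (1 - 0.8)^2 = 0.4, along -x
#' @export
pair_velocity <- function(cell_i, cell_j, params) {
  ci <- cell_row(cell_i); cj <- cell_row(cell_j)
  dvec <- ci$position - cj$position
  d <- sqrt(sum(dvec^2))
  Rsum <- ci$radius + cj$radius
  Asum <- ci$adhesion_distance + cj$adhesion_distance
  if (d >= Asum) return(numeric(length(dvec)))
  if (d < 1e-12) {
    u <- draw_unit_direction(length(dvec))
    return(params$repulsion[ci$type, cj$type] * u)
  }
  u <- dvec / d
  if (d < Rsum) {
    params$repulsion[ci$type, cj$type] * (1 - d / Rsum)^2 * u
  } else {
    -params$adhesion[ci$type, cj$type] * (1 - d / Asum)^2 * u
  }
}

#' Rigid-wall velocity contribution and pressure impulse
#'
#' For each wall closer than the cell radius, adds a repulsion along the
#' inward wall normal with the same quadratic falloff as the cell-cell
#' potential, `boundary_repulsion * (1 - d/R)^2`, and emits an impulse record
#' (wall, AP coordinate, magnitude) used by the boundary-pressure tally.
#' Cells found outside a wall are treated as at zero distance and flagged.
#'
#' @param cell a cell (see [pair_velocity()]).
#' @param geometry a [boundary_geometry()].
#' @param params a [mechanics_params()].
#' @return List with `velocity` and `impulses` (data.frame `wall`, `ap`,
#'   `magnitude`, `clamped`).
#' @export
boundary_velocity <- function(cell, geometry, params) {
  ci <- cell_row(cell)
  pos <- matrix(ci$position, nrow = 1)
  d <- drop(wall_distances(pos, geometry))
  v <- numeric(length(ci$position))
  recs <- list()
  for (w in seq_along(d)) {
    if (d[w] < ci$radius) {
      dd <- max(d[w], 0)
      mag <- params$boundary_repulsion * (1 - dd / ci$radius)^2
      v <- v + mag * geometry$normals[w, ]
      recs[[length(recs) + 1]] <- data.frame(
        wall = rownames(geometry$normals)[w], ap = ci$position[1],
        magnitude = mag, clamped = d[w] < 0)
    }
  }
  imp <- if (length(recs)) do.call(rbind, recs)
         else data.frame(wall = character(), ap = numeric(),
                         magnitude = numeric(), clamped = logical())
  list(velocity = v, impulses = imp)
}

#' Uniform random unit direction
#'
#' @param dimension 2 (unit circle) or 3 (unit sphere).
#' @return Unit vector.
#' @export
draw_unit_direction <- function(dimension = 2) {
  if (dimension == 2) {
    th <- runif(1, 0, 2 * pi)
    c(cos(th), sin(th))
  } else {
    repeat {
      v <- stats::rnorm(3)
      n <- sqrt(sum(v^2))
      if (n > 1e-12) return(v / n)
    }
  }
}

#' Active motility velocity
#'
#' Zero for the passive types (AXIAL, POSTERIOR); for PSM cells, the per-type
#' motility magnitude along the cell's current motility direction.  The
#' direction is directionless noise: it is redrawn uniformly on the unit
#' circle/sphere every `motility_persistence` iterations of a run.
#'
#' @param cell a cell; may carry a `motility_vector` element.
#' @param params a [mechanics_params()].
#' @param redraw if `TRUE` (or if the cell has no stored direction), a new
#'   uniform direction is drawn from the RNG.
#' @return Velocity vector.
#' @export
motility_velocity <- function(cell, params, redraw = FALSE) {
  ci <- cell_row(cell)
  dim <- length(ci$position)
  mag <- unname(params$motility[ci$type])
  if (mag == 0) return(numeric(dim))
  mv <- if (is.data.frame(cell)) NULL else cell$motility_vector
  if (redraw || is.null(mv)) mv <- draw_unit_direction(dim)
  mag * mv
}

#' Reference all-pairs velocity evaluation
#'
#' Computes every cell's passive velocity (pairwise interactions plus wall
#' repulsion, no motility) with an O(N^2) double loop over [pair_velocity()]
#' and [boundary_velocity()].  This is the brute-force oracle the compiled
#' force evaluation is verified against; it is far too slow for production
#' runs.
#'
#' @param cells a cells data.frame.
#' @param geometry a [boundary_geometry()].
#' @param params a [mechanics_params()].
#' @return Matrix (cells x dimension) of velocities.
#' @export
step_velocities <- function(cells, geometry, params) {
  n <- nrow(cells)
  dim <- geometry$dimension
  v <- matrix(0, n, dim)
  cl <- lapply(seq_len(n), function(i) cell_row(cells[i, ]))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) v[i, ] <- v[i, ] + pair_velocity(cl[[i]], cl[[j]], params)
    }
    v[i, ] <- v[i, ] + boundary_velocity(cl[[i]], geometry, params)$velocity
  }
  v
}

#' One iteration of progenitor influx
#'
#' Inserts `rpois(1, rate)` new PSM cells at jittered positions inside the
#' current progenitor domain (the posterior half of the AP window behind
#' the posterior-most axial cell, within the PD midline half-width),
#' rejecting positions closer than one radius to an existing cell (up
#' to 10 attempts each, skipped insertions counted).  This mirrors the rule
#' applied per iteration inside [run_simulation()].
#'
#' @param cells a cells data.frame.
#' @param rate expected insertions per iteration (Poisson).
#' @param pd_halfwidth PD midline half-width.
#' @param pd_depth AP depth of the insertion zone posterior to the axial end.
#' @param dimension 2 or 3.
#' @param zlim DV insertion range (3D).
#' @return List with `cells` (updated) and counts `added`, `skipped`.
#' @export
add_influx <- function(cells, rate, pd_halfwidth = 1, pd_depth = 2,
                       dimension = 2, zlim = c(0.5, 5.5)) {
  stopifnot(rate >= 0)
  k <- rpois(1, rate)
  added <- 0L; skipped <- 0L
  psm_like <- cells$type == "PSM"
  psm_radius <- if (any(psm_like)) stats::median(cells$radius[psm_like])
                else stats::median(cells$radius)
  psm_adh <- psm_radius * 1.25
  min_space <- 1.3 * psm_radius      # 65% of the contact distance
  for (c in seq_len(k)) {
    ax_max <- max(cells$x[cells$type == "AXIAL"])
    placed <- FALSE
    for (att in 1:10) {
      xn <- ax_max + pd_depth * (0.5 + 0.5 * runif(1))
      yn <- (2 * runif(1) - 1) * 0.95 * pd_halfwidth
      zn <- if (dimension == 3) runif(1, zlim[1], zlim[2]) else NULL
      d2 <- (cells$x - xn)^2 + (cells$y - yn)^2 +
        if (dimension == 3) (cells$z - zn)^2 else 0
      if (min(d2) >= min_space^2) {
        new <- data.frame(id = max(cells$id) + 1L, type = "PSM",
                          x = xn, y = yn)
        if (dimension == 3) new$z <- zn
        new$radius <- psm_radius
        new$adhesion_distance <- psm_adh
        if (!is.null(cells$pd)) new$pd <- TRUE
        cells <- rbind(cells, new)
        added <- added + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) skipped <- skipped + 1L
  }
  list(cells = cells, added = added, skipped = skipped)
}
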