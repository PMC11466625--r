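#' Rigid boundary geometry for a tissue construct
#'
#' Defines the rigid confinement of the simulated field: an anterior wall at
#' AP = 0, lateral walls at ML = +/- (axial half-width + PSM width), and, in
#' 3D, dorsal/ventral walls.  The posterior side is never walled: it is either
#' free or capped by passive posterior cells.
#'
#' Axes follow the embryo convention used throughout the package: axis 1 is
#' antero-posterior (AP, increasing posteriorly), axis 2 is medio-lateral
#' (ML, midline at 0), axis 3 (3D only) is dorso-ventral (DV).
#'
#' @param dimension 2 or 3.
#' @param field_length AP extent of the initial construct, in cell-diameter
#'   units (default 15).
#' @param axial_halfwidth half-width of the central axial column (default 1,
#'   i.e. a column two cell diameters wide).
#' @param psm_width ML width of each flanking PSM block (default 4).
#' @param pd_depth AP depth of the posterior progenitor-domain strip
#'   (default 2).  The axial column spans
#'   `field_length - pd_depth - cap_depth`; the PSM blocks flank both the
#'   column and the PD strip.
#' @param cap_depth AP depth of the full-width passive posterior cap
#'   (default 1.4); ignored when `posterior_mode = "FREE"`.
#' @param dv_thickness DV extent of the 3D construct (default 6); ignored in
#'   2D.
#' @param posterior_mode `"PASSIVE_CELLS"` to cap the posterior end with
#'   passive posterior cells, `"FREE"` to leave it open.
#' @return An object of class `boundary_geometry`: a list with the wall
#'   half-spaces (`normals`, inward unit normals; `offsets`; a point `p` is
#'   inside wall `k` when `normals[k, ] %*% p >= offsets[k]`), the layout
#'   dimensions, and `posterior_mode`.
#' @export
boundary_geometry <- function(dimension = 2, field_length = 15,
                              axial_halfwidth = 1.25, psm_width = 3.75,
                              pd_depth = 2, cap_depth = 1.4,
                              dv_thickness = 6,
                              posterior_mode = c("PASSIVE_CELLS", "FREE")) {
  stopifnot(dimension %in% c(2, 3), field_length > pd_depth + cap_depth,
            axial_halfwidth > 0, psm_width > 0, pd_depth > 0, cap_depth > 0)
  posterior_mode <- match.arg(posterior_mode)
  w <- axial_halfwidth + psm_width
  if (dimension == 2) {
    normals <- rbind(anterior = c(1, 0),
                     left     = c(0, 1),
                     right    = c(0, -1))
    offsets <- c(anterior = 0, left = -w, right = -w)
  } else {
    normals <- rbind(anterior = c(1, 0, 0),
                     left     = c(0, 1, 0),
                     right    = c(0, -1, 0),
                     ventral  = c(0, 0, 1),
                     dorsal   = c(0, 0, -1))
    offsets <- c(anterior = 0, left = -w, right = -w,
                 ventral = 0, dorsal = -dv_thickness)
  }
  structure(list(normals = normals, offsets = offsets,
                 dimension = dimension, field_length = field_length,
                 axial_halfwidth = axial_halfwidth, psm_width = psm_width,
                 pd_depth = pd_depth, cap_depth = cap_depth,
                 dv_thickness = dv_thickness,
                 posterior_mode = posterior_mode),
            class = "boundary_geometry")
}

# signed distances of a position matrix to every wall (>= 0 inside)
wall_distances <- function(pos, geometry) {
  pos %*% t(geometry$normals) - rep(geometry$offsets, each = nrow(pos))
}

# jittered lattice of exactly n points filling box [lo, hi] (rows lo/hi per
# axis); returns the unjittered base lattice too so a mirrored block can share
# it.  `drop_seeded` removes surplus lattice sites at random (RNG-dependent).
lattice_fill <- function(lo, hi, n = NULL, spacing = 0.7, jitter = 0.1) {
  ext <- hi - lo
  dim <- length(lo)
  if (is.null(n)) {
    dims <- pmax(1L, as.integer(round(ext / spacing)))
  } else {
    s <- (prod(ext) / n)^(1 / dim)
    dims <- pmax(1L, as.integer(round(ext / s)))
    while (prod(dims) < n) {
      k <- which.max(ext / dims)
      dims[k] <- dims[k] + 1L
    }
  }
  axes <- lapply(seq_len(dim), function(k) {
    step <- ext[k] / dims[k]
    lo[k] + (seq_len(dims[k]) - 0.5) * step
  })
  base <- as.matrix(expand.grid(axes))
  colnames(base) <- NULL
  if (!is.null(n) && nrow(base) > n)
    base <- base[sort(sample.int(nrow(base), n)), , drop = FALSE]
  min_step <- min(ext / dims)
  list(base = base, min_step = min_step)
}

jitter_points <- function(base, jitter) {
  base + matrix(runif(length(base), -jitter, jitter), nrow = nrow(base))
}

#' Build a multi-tissue initial construct
#'
#' Generates the initial condition of the model: a central passive axial
#' column along the AP axis, bilaterally mirror-symmetric motile PSM blocks,
#' a progenitor domain (PD) of PSM-type cells on the posterior midline, and —
#' when `geometry$posterior_mode == "PASSIVE_CELLS"` — mirrored caps of
#' passive posterior cells flanking the PD.  Cells sit on a jittered lattice
#' at near-contact spacing.  Generation is a pure function of
#' `(dimension, counts, geometry, seed)`.
#'
#' Default per-tissue counts are the lattice fills of each tissue region at
#' `spacing`; in 2D this yields a total in the 300-800 range, while the 3D
#' default is adjusted to exactly 7920 cells in total.
#'
#' @param dimension 2 or 3.
#' @param counts optional named list/vector with elements `axial`, `psm`
#'   (per side), `pd` and `posterior` (total, full-width cap); `NULL` for
#'   the defaults.
#' @param geometry a [boundary_geometry()]; must match `dimension`.
#' @param seed integer RNG seed.
#' @param radius cell radius (length units; cell-cell contact distance is
#'   `2 * radius`).
#' @param adhesion_multiplier named per-type multipliers giving the maximum
#'   adhesion distance as `radius * multiplier`.
#' @param spacing named per-tissue lattice spacings (length units).  The
#'   defaults encode the initial mechanical state of each tissue: the
#'   anterior PSM (`PSM`) is packed below contact distance — a compressed,
#'   expanding mesenchyme, the elongation engine — while the posterior PSM
#'   (`PPSM`, the posterior ~5.6 units of the blocks) is sparser than
#'   contact, reproducing the anterior-to-posterior cell-density gradient of
#'   the embryonic PSM; the axial column sits at its force-balance spacing
#'   (stable under the default mechanics); PD and posterior cells at
#'   contact.  A single number is recycled to all tissues.  Explicit
#'   `counts` place each tissue as one uniform block (no PSM gradient).
#' @param jitter uniform jitter half-amplitude per coordinate.
#' @return An object of class `tissue_construct`: list with `cells` (a
#'   data.frame with columns `id`, `type`, `x`, `y`, (`z`,) `radius`,
#'   `adhesion_distance`, `pd` — a logical marking the cells placed as PD),
#'   `geometry`, `dimension`, `seed`.
#' @examples
#' tc <- build_construct(2, seed = 1)
#' nrow(tc$cells)
#' @export
build_construct <- function(dimension = 2, counts = NULL,
                            geometry = boundary_geometry(dimension),
                            seed = 1L, radius = 0.36,
                            adhesion_multiplier = c(AXIAL = 1.1, PSM = 1.25,
                                                    POSTERIOR = 1.1),
                            spacing = c(AXIAL = 0.62, PSM = 0.62,
                                        PPSM = 0.80, PD = 0.72,
                                        POSTERIOR = 0.72),
                            jitter = 0.07) {
  stopifnot(dimension %in% c(2, 3))
  if (length(spacing) == 1)
    spacing <- c(AXIAL = spacing, PSM = spacing, PPSM = spacing,
                 PD = spacing, POSTERIOR = spacing)
  if (!"PPSM" %in% names(spacing))
    spacing["PPSM"] <- spacing["PSM"]
  stopifnot(all(c("AXIAL", "PSM", "PPSM", "PD", "POSTERIOR") %in%
                  names(spacing)))
  if (geometry$dimension != dimension)
    stop("geometry dimension (", geometry$dimension,
         ") does not match `dimension` (", dimension, ")")
  set.seed(as.integer(seed))

  g <- geometry
  cap <- if (g$posterior_mode == "PASSIVE_CELLS") g$cap_depth else 0
  ax_len <- g$field_length - g$pd_depth - cap
  hw <- g$axial_halfwidth
  w <- hw + g$psm_width
  z_rng <- if (dimension == 3) c(0, g$dv_thickness) else NULL
  box <- function(x0, x1, y0, y1) {
    if (dimension == 2) list(lo = c(x0, y0), hi = c(x1, y1))
    else list(lo = c(x0, y0, z_rng[1]), hi = c(x1, y1, z_rng[2]))
  }
  # the axial column ends at ax_len; the PD strip continues the midline and
  # is flanked by the PSM blocks; a full-width passive cap closes the field.
  # The PSM blocks are split into a dense anterior part and a sparse
  # posterior (pPSM) part starting 4 units anterior of the column tip.
  psm_split <- max(0, ax_len - 4)
  regions <- list(
    axial     = box(0, ax_len, -hw, hw),
    psm       = box(0, psm_split, -w, -hw),         # left blocks; mirrored
    ppsm      = box(psm_split, ax_len + g$pd_depth, -w, -hw),
    pd        = box(ax_len, ax_len + g$pd_depth, -hw, hw),
    posterior = box(ax_len + g$pd_depth, g$field_length, -w, w))

  region_spacing <- c(axial = unname(spacing["AXIAL"]),
                      psm = unname(spacing["PSM"]),
                      ppsm = unname(spacing["PPSM"]),
                      pd = unname(spacing["PD"]),
                      posterior = unname(spacing["POSTERIOR"]))

  want_post <- g$posterior_mode == "PASSIVE_CELLS"
  fill_mode <- is.null(counts)
  psm_n <- pd_n <- NULL   # NULL = fill the region at its tissue spacing
  if (fill_mode) {
    counts <- lapply(names(regions), function(nm) {
      r <- regions[[nm]]
      nrow(lattice_fill(r$lo, r$hi, spacing = region_spacing[nm])$base)
    })
    names(counts) <- names(regions)
    if (!want_post) counts$posterior <- 0L
    if (dimension == 3) {
      # hit the 3D reference field size exactly by sizing the PSM blocks
      others <- counts$axial + counts$pd + counts$posterior +
        2L * counts$ppsm
      counts$psm <- (7920L - others) %/% 2L
      counts$pd <- counts$pd + (7920L - others - 2L * counts$psm)
      psm_n <- counts$psm
      pd_n <- counts$pd
    }
  } else {
    # explicit counts: one uniform PSM block per side spanning the whole
    # flank (no anterior/posterior gradient)
    regions$psm[["hi"]][1] <- regions$ppsm[["hi"]][1]
    counts$ppsm <- 0L
    psm_n <- counts$psm
    pd_n <- counts$pd
  }
  counts <- lapply(counts, as.integer)
  if (!want_post && isTRUE(counts$posterior > 0))
    stop("posterior counts > 0 but posterior_mode is FREE")

  # capacity check: per-tissue lattice spacing must stay above one radius
  check_capacity <- function(name, region, n) {
    if (n <= 0) return(invisible())
    lf <- lattice_fill(region$lo, region$hi, n = n)
    if (lf$min_step < radius)
      stop("counts exceed geometric capacity at minimum spacing for tissue ",
           name)
    invisible()
  }
  check_capacity("axial", regions$axial, counts$axial)
  check_capacity("psm", regions$psm, counts$psm)
  check_capacity("pd", regions$pd, counts$pd)
  if (want_post) check_capacity("posterior", regions$posterior, counts$posterior)

  mirror <- function(p) { p[, 2] <- -p[, 2]; p }
  place <- function(nm, n) {
    # n = NULL fills the region at the tissue spacing; otherwise the lattice
    # dimensions are derived from the requested count
    if (!is.null(n) && n <= 0) return(NULL)
    region <- regions[[nm]]
    base <- lattice_fill(region$lo, region$hi, n = n,
                         spacing = region_spacing[nm])$base
    jitter_points(base, jitter)
  }
  ax <- place("axial", if (fill_mode) NULL else counts$axial)
  psm_l <- place("psm", psm_n)
  ppsm_l <- if (fill_mode) place("ppsm", NULL) else NULL
  psm_l <- rbind(psm_l, ppsm_l)
  psm_r <- if (is.null(psm_l)) NULL else mirror(psm_l)
  pd <- place("pd", pd_n)
  post <- if (want_post)
    place("posterior", if (fill_mode) NULL else counts$posterior) else NULL

  pos <- rbind(ax, psm_l, psm_r, pd, post)
  types <- c(rep("AXIAL", NROW(ax)),
             rep("PSM", NROW(psm_l) + NROW(psm_r) + NROW(pd)),
             rep("POSTERIOR", NROW(post)))
  is_pd <- c(rep(FALSE, NROW(ax) + NROW(psm_l) + NROW(psm_r)),
             rep(TRUE, NROW(pd)),
             rep(FALSE, NROW(post)))

  cells <- data.frame(id = seq_len(nrow(pos)), type = types,
                      x = pos[, 1], y = pos[, 2])
  if (dimension == 3) cells$z <- pos[, 3]
  cells$radius <- radius
  cells$adhesion_distance <- radius * unname(adhesion_multiplier[cells$type])
  cells$pd <- is_pd

  structure(list(cells = cells, geometry = g, dimension = dimension,
                 counts = counts, seed = as.integer(seed)),
            class = "tissue_construct")
}

#' @export
print.tissue_construct <- function(x, ...) {
  tab <- table(x$cells$type)
  cat("Tissue construct (", x$dimension, "D), ", nrow(x$cells), " cells: ",
      paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n  field length ", x$geometry$field_length,
      ", posterior mode ", x$geometry$posterior_mode,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
plot.tissue_construct <- function(x, ...) {
  cols <- c(AXIAL = "goldenrod", PSM = "grey40", POSTERIOR = "steelblue")
  plot(x$cells$x, x$cells$y, col = cols[x$cells$type], pch = 16, cex = 0.5,
       xlab = "AP (length units)", ylab = "ML (length units)", asp = 1, ...)
  invisible(x)
}

# coerce a construct/snapshot-like object to its cells data.frame
as_cells <- function(x) {
  if (inherits(x, "tissue_construct")) x$cells
  else if (is.data.frame(x)) x
  else stop("expected a tissue_construct or a cells data.frame")
}

#' Progenitor-domain mask
#'
#' Identifies the PSM progenitors of the progenitor domain (PD): PSM cells
#' whose AP coordinate is posterior to the posterior-most axial cell and whose
#' |ML| coordinate is within `halfwidth` of the midline.  The mask is
#' recomputable on any state of a running simulation.
#'
#' @param x a `tissue_construct` or a cells data.frame with columns
#'   `type`, `x`, `y`, `id`.
#' @param halfwidth midline half-width (default 1 cell diameter).
#' @return Integer vector of cell ids in the PD.
#' @export
pd_mask <- function(x, halfwidth = 1) {
  cells <- as_cells(x)
  ax <- cells$x[cells$type == "AXIAL"]
  if (length(ax) == 0) stop("pd_mask requires at least one AXIAL cell")
  sel <- cells$type == "PSM" & cells$x > max(ax) & abs(cells$y) <= halfwidth
  cells$id[sel]
}
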