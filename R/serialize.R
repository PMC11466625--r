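#' Write / read a tissue construct as CSV
#'
#' Columns: `id`, `type`, `x`, `y` (, `z`), `radius`, `adhesion_distance`,
#' `pd`.  The boundary geometry is not stored in the CSV; supply it on read.
#'
#' @param construct a `tissue_construct`.
#' @param path CSV file path.
#' @export
write_construct <- function(construct, path) {
  write.csv(construct$cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_construct
#' @param geometry a [boundary_geometry()] matching the stored layout.
#' @param seed the seed recorded on the returned construct (bookkeeping
#'   only).
#' @export
read_construct <- function(path, geometry = NULL, seed = NA_integer_) {
  cells <- read.csv(path, stringsAsFactors = FALSE)
  dimension <- if ("z" %in% names(cells)) 3L else 2L
  if (is.null(geometry)) geometry <- boundary_geometry(dimension)
  structure(list(cells = cells, geometry = geometry, dimension = dimension,
                 counts = NULL, seed = seed), class = "tissue_construct")
}

#' Write / read mechanics parameters as YAML
#'
#' @param params a [mechanics_params()].
#' @param path YAML file path.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(list(
    repulsion = as.list(as.data.frame(params$repulsion)),
    adhesion = as.list(as.data.frame(params$adhesion)),
    motility = as.list(params$motility),
    adhesion_multiplier = as.list(params$adhesion_multiplier),
    boundary_repulsion = params$boundary_repulsion,
    dt = params$dt, motility_persistence = params$motility_persistence,
    step_clamp = params$step_clamp), path, precision = 15L)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  y <- yaml::read_yaml(path)
  tn <- names(TISSUE_TYPES)
  as_mat <- function(l) {
    m <- do.call(cbind, l[tn])
    rownames(m) <- tn
    m[tn, tn]
  }
  p <- mechanics_params(
    motility = unlist(y$motility)[tn],
    adhesion_multiplier = unlist(y$adhesion_multiplier)[tn],
    boundary_repulsion = y$boundary_repulsion,
    dt = y$dt, motility_persistence = y$motility_persistence,
    step_clamp = y$step_clamp)
  p$repulsion <- as_mat(y$repulsion)
  p$adhesion <- as_mat(y$adhesion)
  p
}
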