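#' Repulsion sweep ranges
#'
#' The explored ranges of the five cell-cell repulsion parameters of the 2D
#' model: PSM-PSM 5-45, NC-NC (axial) 1-16, Posterior-Posterior 0.1-1.1,
#' PSM-NC 20-80, PSM-Posterior 10-60.
#'
#' @return Named list of `c(min, max)` ranges.
#' @export
sweep_ranges <- function() {
  list(psm_psm = c(5, 45), nc_nc = c(1, 16), post_post = c(0.1, 1.1),
       psm_nc = c(20, 80), psm_post = c(10, 60))
}

#' Min-max scale / unscale sweep parameters
#'
#' @param x named numeric vector or data.frame of raw (or scaled) values.
#' @param ranges ranges as from [sweep_ranges()].
#' @return Scaled values in \[0, 1\] (or raw values for `unscale_params`).
#' @export
scale_params <- function(x, ranges = sweep_ranges()) {
  nm <- if (is.data.frame(x)) names(x) else names(x)
  out <- x
  for (p in intersect(nm, names(ranges))) {
    r <- ranges[[p]]
    if (is.data.frame(out)) out[[p]] <- (out[[p]] - r[1]) / (r[2] - r[1])
    else out[p] <- (out[p] - r[1]) / (r[2] - r[1])
  }
  out
}

#' @rdname scale_params
#' @export
unscale_params <- function(x, ranges = sweep_ranges()) {
  nm <- names(x)
  out <- x
  for (p in intersect(nm, names(ranges))) {
    r <- ranges[[p]]
    if (is.data.frame(out)) out[[p]] <- r[1] + out[[p]] * (r[2] - r[1])
    else out[p] <- r[1] + out[p] * (r[2] - r[1])
  }
  out
}

#' Generate sweep input points
#'
#' Either the full tensor grid over all five repulsion parameters, or a 1D
#' slice varying one parameter over its range with the others held at their
#' range midpoints.
#'
#' @param ranges as [sweep_ranges()].
#' @param points_per_axis number of evenly spaced points (>= 2).
#' @param mode `"one_axis_slice"` or `"full_grid"`.
#' @param vary parameter varied by the slice (default `"psm_psm"`).
#' @return Data.frame with one row per point: the five raw parameters, their
#'   min-max scaled counterparts (`scaled_*`), and `point` ids.
#' @examples
#' g <- generate_grid(points_per_axis = 9)
#' g$psm_psm           # 5, 10, ..., 45
#' @export
generate_grid <- function(ranges = sweep_ranges(), points_per_axis = 17,
                          mode = c("one_axis_slice", "full_grid"),
                          vary = "psm_psm") {
  mode <- match.arg(mode)
  stopifnot(points_per_axis >= 2)
  if (mode == "one_axis_slice") {
    stopifnot(vary %in% names(ranges))
    pts <- lapply(names(ranges), function(p) {
      r <- ranges[[p]]
      if (p == vary) seq(r[1], r[2], length.out = points_per_axis)
      else mean(r)
    })
    names(pts) <- names(ranges)
    out <- data.frame(pts)
  } else {
    axes <- lapply(ranges, function(r) seq(r[1], r[2],
                                           length.out = points_per_axis))
    out <- expand.grid(axes)
  }
  sc <- scale_params(out, ranges)
  names(sc) <- paste0("scaled_", names(sc))
  out <- cbind(point = seq_len(nrow(out)), out, sc)
  attr(out, "vary") <- if (mode == "one_axis_slice") vary else NA_character_
  out
}

#' Run a repulsion parameter sweep
#'
#' Runs the 2D model without progenitor influx at each sweep point, with
#' `replicates` independent seeds per point, and records the axial-tissue
#' minimum-bounding-box length and width plus the convergence/elongation
#' regime classification of every run.  Individual run failures are flagged
#' and the sweep continues.  Results are deterministic per
#' `(seed, point, replicate)`.
#'
#' @param points data.frame from [generate_grid()].
#' @param replicates seeds per point.
#' @param n_iterations iterations per run (default 4000).
#' @param seed root seed; per-run seeds are derived from it.
#' @param params_fn function(row) -> [mechanics_params()]; the default
#'   installs the row's five repulsion values (homotypic on the diagonal,
#'   PSM-NC and PSM-Posterior as pair overrides) with all other parameters
#'   at their defaults.
#' @param construct_fn function(seed) -> [build_construct()]; default: the
#'   default 2D construct with passive posterior cells.
#' @return Data.frame, one row per point x replicate: parameters (raw and
#'   scaled), `length`, `width` (axial bounding box), `ratio`, `label`,
#'   `seed`, `ok`.
#' @export
run_sweep <- function(points, replicates = 5, n_iterations = 4000,
                      seed = 1L, params_fn = NULL, construct_fn = NULL) {
  stopifnot(replicates >= 1)
  if (is.null(params_fn)) {
    params_fn <- function(row) {
      mechanics_params(
        repulsion = c(AXIAL = row$nc_nc, PSM = row$psm_psm,
                      POSTERIOR = row$post_post),
        repulsion_pairs = c("PSM-AXIAL" = row$psm_nc,
                            "PSM-POSTERIOR" = row$psm_post))
    }
  }
  if (is.null(construct_fn)) {
    # the simplified sweep model: uniformly compressed PSM blocks (the
    # expansion reservoir probed by the repulsion coefficients) and a
    # slightly slack axial column whose cohesion can drive convergence
    construct_fn <- function(s)
      build_construct(2, seed = s,
                      spacing = c(AXIAL = 0.78, PSM = 0.64, PPSM = 0.64,
                                  PD = 0.72, POSTERIOR = 0.72))
  }
  rows <- list()
  for (i in seq_len(nrow(points))) {
    row <- points[i, ]
    params <- params_fn(row)
    for (r in seq_len(replicates)) {
      run_seed <- sweep_seed(seed, i, r)
      res <- tryCatch({
        tc <- construct_fn(run_seed)
        tr <- run_simulation(tc, params, n_iterations = n_iterations,
                             influx_rate = 0,
                             record_every = n_iterations, seed = run_seed)
        fin <- tr$final
        axc <- fin[fin$type == "AXIAL", ]
        reg <- classify_regime(tr)
        data.frame(length = max(axc$x) - min(axc$x),
                   width = max(axc$y) - min(axc$y),
                   ratio = reg$ratio, label = reg$label,
                   seed = run_seed, ok = TRUE)
      }, error = function(e) {
        warning("sweep point ", row$point, " replicate ", r, " failed: ",
                conditionMessage(e))
        data.frame(length = NA_real_, width = NA_real_, ratio = NA_real_,
                   label = NA_character_, seed = run_seed, ok = FALSE)
      })
      rows[[length(rows) + 1]] <- cbind(row, replicate = r, res,
                                        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "vary") <- attr(points, "vary")
  out
}

# deterministic per-(point, replicate) seed below 2^31
sweep_seed <- function(seed, i, r) {
  as.integer((as.numeric(seed) %% 1e6) * 1000 + i * 37 + r)
}

#' Locate the regime-transition boundary on a sweep slice
#'
#' Majority-votes the regime label per point across replicates and returns
#' the scaled midpoint between the highest convergence-dominated and lowest
#' elongation-dominated points.  The slice is assumed monotone (convergence
#' at low values, elongation at high); when replicate noise makes the voted
#' label sequence non-monotone, the assumed monotonicity is enforced
#' instead: an isotonic (pool-adjacent-violators) fit of the per-point
#' elongation-vote share is computed and the transition reported where the
#' fitted share crosses 1/2.  Non-monotone slices are flagged via the
#' `monotone` attribute and a warning.
#'
#' @param slice data.frame from [run_sweep()] over a one-axis slice.
#' @param vary varied parameter name (default: taken from the slice's
#'   attribute).
#' @return Scaled transition value, with attributes `interval` (the
#'   bracketing scaled values) and `monotone`.
#' @export
find_transition <- function(slice, vary = NULL) {
  if (is.null(vary)) vary <- attr(slice, "vary")
  if (is.null(vary) || is.na(vary)) stop("no varied parameter identified")
  sc <- slice[[paste0("scaled_", vary)]]
  ok <- !is.na(slice$label)
  vote <- tapply(slice$label[ok], sc[ok], function(l)
    names(sort(table(l), decreasing = TRUE))[1])
  eshare <- tapply(slice$label[ok] == "ELONGATION", sc[ok], mean)
  v <- as.numeric(names(vote))
  ord <- order(v)
  v <- v[ord]; vote <- vote[ord]; eshare <- as.numeric(eshare)[ord]
  if (!any(vote == "CONVERGENCE") || !any(vote == "ELONGATION"))
    stop("no transition in range: slice contains a single regime")
  hi_c <- max(v[vote == "CONVERGENCE"])
  lo_e <- min(v[vote == "ELONGATION"])
  monotone <- all(v[vote == "ELONGATION"] > hi_c) &&
    all(v[vote == "CONVERGENCE"] < lo_e)
  if (monotone)
    return(structure((hi_c + lo_e) / 2, interval = c(hi_c, lo_e),
                     monotone = TRUE))
  warning("voted labels are not monotone; reporting the isotonic-fit ",
          "crossing of the elongation-vote share")
  iso <- stats::isoreg(v, eshare)
  yf <- iso$yf
  cross <- which(yf >= 0.5)[1]
  if (is.na(cross)) cross <- length(v)
  if (cross == 1L) {
    est <- v[1]
  } else {
    # linear interpolation inside the step that crosses 1/2
    x0 <- v[cross - 1]; x1 <- v[cross]
    y0 <- yf[cross - 1]; y1 <- yf[cross]
    est <- if (y1 > y0) x0 + (0.5 - y0) / (y1 - y0) * (x1 - x0)
           else (x0 + x1) / 2
  }
  structure(est, interval = c(hi_c, lo_e), monotone = FALSE)
}

#' Fit a shallow neural-network surrogate of sweep outputs
#'
#' Trains a one-hidden-layer feed-forward regressor from the five min-max
#' scaled repulsion parameters to the min-max scaled axial length and width,
#' with a 70/15/15 train/validation/test split.  Both inputs and outputs are
#' scaled before training; the validation set selects the weight-decay
#' setting, and the held-out test R-squared is reported.
#'
#' @param results data.frame from [run_sweep()] (needs the `scaled_*` columns
#'   and `length`, `width`); rows with failed runs are dropped.
#' @param hidden_units hidden-layer size (default 10).
#' @param split_seed seed of the random split.
#' @param decay_grid weight-decay values tried against the validation set.
#' @param maxit optimizer iteration cap.
#' @return Object of class `axis_surrogate`: the fitted `nnet`, the scaling
#'   of the targets, the split indices, validation MSEs, and `r2_test`.
#' @export
fit_surrogate <- function(results, hidden_units = 10, split_seed = 1L,
                          decay_grid = c(1e-4, 1e-3, 1e-2), maxit = 500) {
  keep <- stats::complete.cases(results[, c("length", "width")])
  results <- results[keep, , drop = FALSE]
  n <- nrow(results)
  if (n < 50) stop("need at least 50 completed sweep points")
  xcols <- paste0("scaled_", names(sweep_ranges()))
  X <- as.matrix(results[, xcols])
  Yraw <- as.matrix(results[, c("length", "width")])
  lo <- apply(Yraw, 2, min); hi <- apply(Yraw, 2, max)
  if (any(hi - lo < 1e-12)) stop("degenerate (constant) targets")
  Y <- base::sweep(base::sweep(Yraw, 2, lo, "-"), 2, hi - lo, "/")

  set.seed(as.integer(split_seed))
  n_train <- round(0.70 * n); n_val <- round(0.15 * n)
  idx <- sample.int(n)
  split <- list(train = idx[seq_len(n_train)],
                val = idx[n_train + seq_len(n_val)],
                test = idx[(n_train + n_val + 1):n])

  mse <- function(fit, rows) {
    p <- predict(fit, X[rows, , drop = FALSE])
    mean((p - Y[rows, , drop = FALSE])^2)
  }
  fits <- lapply(decay_grid, function(dc)
    nnet::nnet(X[split$train, ], Y[split$train, ], size = hidden_units,
               linout = TRUE, decay = dc, maxit = maxit, trace = FALSE))
  val_mse <- vapply(fits, mse, numeric(1), rows = split$val)
  best <- fits[[which.min(val_mse)]]

  pt <- predict(best, X[split$test, , drop = FALSE])
  yt <- Y[split$test, , drop = FALSE]
  r2 <- mean(vapply(seq_len(ncol(yt)), function(k) {
    ss_res <- sum((pt[, k] - yt[, k])^2)
    ss_tot <- sum((yt[, k] - mean(yt[, k]))^2)
    1 - ss_res / ss_tot
  }, numeric(1)))

  structure(list(fit = best, target_lo = lo, target_hi = hi,
                 split = split, decay = decay_grid[which.min(val_mse)],
                 val_mse = val_mse, r2_test = r2,
                 hidden_units = hidden_units),
            class = "axis_surrogate")
}

#' @export
print.axis_surrogate <- function(x, ...) {
  cat("Shallow network surrogate: ", x$hidden_units, " hidden units, decay ",
      x$decay, "\n  held-out test R^2 = ", round(x$r2_test, 4),
      " (train/val/test ", length(x$split$train), "/", length(x$split$val),
      "/", length(x$split$test), ")\n", sep = "")
  invisible(x)
}

#' Predict axial length/width from a fitted surrogate
#'
#' @param object an `axis_surrogate`.
#' @param newdata data.frame with the five `scaled_*` input columns (or raw
#'   parameter columns, which are scaled first).
#' @param ... unused.
#' @return Matrix with columns `length`, `width` on the original scale.
#' @export
predict.axis_surrogate <- function(object, newdata, ...) {
  xcols <- paste0("scaled_", names(sweep_ranges()))
  if (!all(xcols %in% names(newdata))) {
    sc <- scale_params(newdata[, names(sweep_ranges())])
    names(sc) <- xcols
    newdata <- sc
  }
  p <- predict(object$fit, as.matrix(newdata[, xcols]))
  out <- base::sweep(base::sweep(p, 2, object$target_hi - object$target_lo,
                                 "*"), 2, object$target_lo, "+")
  colnames(out) <- c("length", "width")
  out
}
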