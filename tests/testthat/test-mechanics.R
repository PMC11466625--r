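test_that("pair velocities follow the quadratic contact potentials", {
  p <- mechanics_params(repulsion = c(AXIAL = 10, PSM = 10, POSTERIOR = 10))
  mk <- function(x, type = "PSM", r = 0.5, a = 0.625)
    list(position = c(x, 0), type = type, radius = r, adhesion_distance = a)

  # beyond adhesion range: zero
  expect_equal(pair_velocity(mk(0), mk(1.3), p), c(0, 0))

  # overlapping: repulsion 10 * (1 - 0.8/1)^2 = 0.4 along j -> i
  v <- pair_velocity(mk(0), mk(0.8), p)
  expect_equal(v, c(-0.4, 0))

  # adhesive shell (1.0 <= d < 1.25): attraction toward j
  va <- pair_velocity(mk(0), mk(1.1), p)
  expect_lt(sqrt(sum(va^2)), 0.05)   # small magnitude
  expect_gt(va[1], 0)                # toward the neighbour

  # antisymmetry for identical cells
  a <- mk(0); b <- mk(0.6)
  expect_equal(pair_velocity(a, b, p), -pair_velocity(b, a, p))

  # magnitude uses the geometric mean of per-type coefficients
  p2 <- mechanics_params(repulsion = c(AXIAL = 40, PSM = 10, POSTERIOR = 10),
                         repulsion_pairs = NULL)
  v2 <- pair_velocity(mk(0, "AXIAL", a = 0.55), mk(0.8), p2)
  expect_equal(v2[1], -sqrt(40 * 10) * (1 - 0.8)^2)
})

test_that("wall repulsion has the documented magnitude and direction", {
  g <- boundary_geometry(2)
  p <- mechanics_params(boundary_repulsion = 10)
  w <- g$axial_halfwidth + g$psm_width
  # cell at distance 0.25 from the left lateral wall, radius 0.5
  cell <- list(position = c(5, -(w - 0.25)), type = "PSM", radius = 0.5,
               adhesion_distance = 0.625)
  bv <- boundary_velocity(cell, g, p)
  expect_equal(bv$velocity[2], 10 * (1 - 0.25 / 0.5)^2)  # toward midline
  expect_equal(bv$impulses$magnitude, 2.5)
  expect_false(bv$impulses$clamped)

  # far from every wall: nothing
  far <- list(position = c(7, 0), type = "PSM", radius = 0.5,
              adhesion_distance = 0.625)
  bv2 <- boundary_velocity(far, g, p)
  expect_equal(bv2$velocity, c(0, 0))
  expect_identical(nrow(bv2$impulses), 0L)

  # outside the wall: clamped flag, full-strength push
  out <- list(position = c(-0.2, 0), type = "PSM", radius = 0.5,
              adhesion_distance = 0.625)
  bv3 <- boundary_velocity(out, g, p)
  expect_true(bv3$impulses$clamped[1])
  expect_equal(bv3$velocity[1], 10)
})

test_that("motility is zero for passive types and isotropic for PSM", {
  p <- mechanics_params()
  ax <- list(position = c(0, 0), type = "AXIAL", radius = 0.36,
             adhesion_distance = 0.396)
  po <- list(position = c(0, 0), type = "POSTERIOR", radius = 0.36,
             adhesion_distance = 0.396)
  expect_equal(motility_velocity(ax, p), c(0, 0))
  expect_equal(motility_velocity(po, p), c(0, 0))

  psm <- list(position = c(0, 0), type = "PSM", radius = 0.36,
              adhesion_distance = 0.45)
  set.seed(1)
  v <- motility_velocity(psm, p, redraw = TRUE)
  expect_equal(sqrt(sum(v^2)), 1.2)

  # directionless: mean direction vanishes over many redraws
  set.seed(2)
  dirs <- t(replicate(10000, draw_unit_direction(2)))
  expect_lt(max(abs(colMeans(dirs))), 0.02)
  expect_equal(rowSums(dirs^2), rep(1, 10000))
})

test_that("a frozen system is a fixed point of the integrator", {
  tc <- tiny_construct()
  tr <- run_simulation(tc, frozen_params(), n_iterations = 20,
                       record_every = 20, seed = 1)
  expect_equal(tr$final$x, tc$cells$x)
  expect_equal(tr$final$y, tc$cells$y)
  expect_equal(tr$n_clamped, 0L)
})

test_that("a single free motile cell moves at the motility speed", {
  g <- boundary_geometry(2, posterior_mode = "FREE")
  cells <- data.frame(id = 1:5, type = c(rep("AXIAL", 4), "PSM"),
                      x = c(1, 2, 3, 4, 40), y = c(0, 0, 0, 0, 0),
                      radius = 0.36,
                      adhesion_distance = c(rep(0.396, 4), 0.45),
                      pd = FALSE)
  tc <- structure(list(cells = cells, geometry = g, dimension = 2,
                       counts = NULL, seed = 1L), class = "tissue_construct")
  # persistence longer than the run: one direction, ballistic motion
  p <- mechanics_params(motility_persistence = 1000L)
  tr <- run_simulation(tc, p, n_iterations = 100, record_every = 100,
                       seed = 3)
  d <- sqrt((tr$final$x[5] - 40)^2 + tr$final$y[5]^2)
  expect_equal(d, 1.2 * p$dt * 100, tolerance = 1e-10)
})

test_that("compiled forces equal the all-pairs R oracle", {
  tc <- tiny_construct(seed = 7)
  p <- mechanics_params(motility = c(AXIAL = 0, PSM = 0, POSTERIOR = 0))
  # one compiled step
  tr <- run_simulation(tc, p, n_iterations = 1, record_every = 1, seed = 1)
  # R reference: velocities from pair_velocity/boundary_velocity loops
  v <- step_velocities(tc$cells, tc$geometry, p)
  expected_x <- tc$cells$x + v[, 1] * p$dt
  expected_y <- tc$cells$y + v[, 2] * p$dt
  expect_equal(tr$final$x, expected_x, tolerance = 1e-12)
  expect_equal(tr$final$y, expected_y, tolerance = 1e-12)
})

test_that("binned neighbour search matches brute force over a full run", {
  tc <- tiny_construct(seed = 2)
  p <- mechanics_params()
  a <- run_simulation(tc, p, n_iterations = 50, record_every = 50, seed = 5,
                      neighbor_search = "bins")
  b <- run_simulation(tc, p, n_iterations = 50, record_every = 50, seed = 5,
                      neighbor_search = "brute")
  expect_equal(a$final$x, b$final$x, tolerance = 1e-10)
  expect_equal(a$final$y, b$final$y, tolerance = 1e-10)
})

test_that("an isolated identical pair displaces antisymmetrically", {
  g <- boundary_geometry(2, posterior_mode = "FREE")
  cells <- data.frame(id = 1:6, type = c(rep("AXIAL", 4), "PSM", "PSM"),
                      x = c(1, 2, 3, 4, 30, 30.5),
                      y = c(0, 0, 0, 0, 2, 2),
                      radius = 0.36,
                      adhesion_distance = c(rep(0.396, 4), 0.45, 0.45),
                      pd = FALSE)
  tc <- structure(list(cells = cells, geometry = g, dimension = 2,
                       counts = NULL, seed = 1L), class = "tissue_construct")
  p <- mechanics_params(motility = c(AXIAL = 0, PSM = 0, POSTERIOR = 0))
  tr <- run_simulation(tc, p, n_iterations = 10, record_every = 10, seed = 1)
  d5 <- c(tr$final$x[5] - 30, tr$final$y[5] - 2)
  d6 <- c(tr$final$x[6] - 30.5, tr$final$y[6] - 2)
  expect_equal(d5, -d6, tolerance = 1e-12)
  expect_gt(abs(d5[1]), 0)
})

test_that("identical seeds give bit-identical trajectories", {
  tc <- tiny_construct(seed = 3)
  p <- mechanics_params()
  a <- run_simulation(tc, p, n_iterations = 80, influx_rate = 0.3,
                      record_every = 40, seed = 11)
  b <- run_simulation(tc, p, n_iterations = 80, influx_rate = 0.3,
                      record_every = 40, seed = 11)
  expect_identical(a$final, b$final)
  expect_identical(a$length_series, b$length_series)
  c <- run_simulation(tc, p, n_iterations = 80, influx_rate = 0.3,
                      record_every = 40, seed = 12)
  expect_false(identical(a$final$x, c$final$x))
})

test_that("cell count is conserved without influx and grows like Poisson with it", {
  tc <- tiny_construct(seed = 4)
  p <- mechanics_params()
  tr0 <- run_simulation(tc, p, n_iterations = 200, influx_rate = 0,
                        record_every = 200, seed = 2)
  expect_identical(nrow(tr0$final), nrow(tc$cells))

  # sparse posterior region so insertions are rarely rejected
  g <- boundary_geometry(2, posterior_mode = "FREE")
  few <- build_construct(2, counts = list(axial = 30, psm = 12, pd = 2,
                                          posterior = 0),
                         geometry = g, seed = 1)
  p_frozen <- mechanics_params(motility = c(AXIAL = 0, PSM = 1.2,
                                            POSTERIOR = 0))
  tr <- run_simulation(few, p_frozen, n_iterations = 2000,
                       influx_rate = 0.5, record_every = 1000, seed = 9,
                       influx_min_space = 1.0)
  n_added <- tr$n_added + tr$n_skipped
  # total attempted insertions are exactly Poisson(0.5) per iteration
  expect_lt(abs(n_added - 1000), 3 * sqrt(1000))
  expect_identical(nrow(tr$final), nrow(few$cells) + tr$n_added)

  # all inserted cells are PSM
  new <- tr$final[tr$final$id > max(few$cells$id), ]
  expect_true(all(new$type == "PSM"))
})

test_that("add_influx inserts PD-compatible PSM cells", {
  st <- data.frame(id = 1:5, type = c(rep("AXIAL", 4), "PSM"),
                   x = c(1, 2, 3, 4, 8), y = c(0, 0, 0, 0, 3),
                   radius = 0.36,
                   adhesion_distance = c(rep(0.396, 4), 0.45))
  set.seed(21)
  res <- add_influx(st, rate = 30, pd_halfwidth = 1.5, pd_depth = 2)
  expect_gt(res$added, 0)
  new <- res$cells[res$cells$id > 5, ]
  expect_true(all(new$type == "PSM"))
  # every inserted cell passes pd_mask at the insertion half-width
  expect_true(all(new$id %in% pd_mask(res$cells, halfwidth = 1.5)))
})

test_that("expansion drives axial elongation across seeds", {
  # default construct and mechanics: the compressed anterior PSM expands and
  # the confined field extends posteriorly
  gain <- vapply(1:10, function(s) {
    tc <- build_construct(2, seed = s)
    tr <- run_simulation(tc, mechanics_params(), n_iterations = 2000,
                         record_every = 2000, seed = s)
    ax0 <- tc$cells$x[tc$cells$type == "AXIAL"]
    ax1 <- tr$final$x[tr$final$type == "AXIAL"]
    (max(ax1) - min(ax1)) - (max(ax0) - min(ax0))
  }, numeric(1))
  expect_gt(mean(gain), 0)
})

test_that("mechanics params YAML round-trips", {
  p <- mechanics_params(repulsion = c(AXIAL = 8.5, PSM = 25, POSTERIOR = 0.6),
                        repulsion_pairs = c("PSM-AXIAL" = 50))
  path <- tempfile(fileext = ".yaml")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(q$repulsion, p$repulsion)
  expect_equal(q$adhesion, p$adhesion)
  expect_equal(q$dt, p$dt)
  unlink(path)
})
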