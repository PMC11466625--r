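test_that("axis_length averages the 4 posterior-most axial cells", {
  st <- hand_state()
  # axial cells at AP 1..5: mean of (5, 4, 3, 2) = 3.5
  expect_equal(axis_length(st), 3.5)

  # rigid translation with the wall fixed adds the shift
  st2 <- st
  st2$x <- st2$x + 2
  expect_equal(axis_length(st2), 5.5)

  # exactly 4 axial cells: their plain mean
  st3 <- st[st$id != 5, ]
  expect_equal(axis_length(st3), mean(c(1, 2, 3, 4)))

  expect_error(axis_length(st[st$type == "PSM", ]), "AXIAL")

  # id relabeling leaves the measure unchanged (no AP ties here)
  st4 <- st
  st4$id <- rev(st4$id)
  expect_equal(axis_length(st4), axis_length(st))
})

test_that("elongation extent is 1 under frozen dynamics", {
  tc <- tiny_construct()
  spec <- perturbation("GLOBAL_STRAIN", strain = 0.10,
                       apply_at_iteration = 5)
  tr <- run_simulation(tc, frozen_params(), n_iterations = 10,
                       perturbation = spec, record_every = 5, seed = 1)
  expect_equal(elongation_extent(tr), 1.0, tolerance = 1e-12)

  # under frozen dynamics a 10% stretch leaves final length = 1.1 * initial,
  # so extent relative to the unperturbed reference is 1/1.1
  l0 <- axis_length(get_snapshot(tr, 1))
  lf <- axis_length(tr$final)
  expect_equal(lf, 1.1 * l0, tolerance = 1e-12)
})

test_that("density profile is flat on a uniform lattice and halves under deletion", {
  # hand-built uniform PSM lattice flanking a 10-unit axial column
  xs <- seq(0.5, 9.5, by = 1)
  ys <- seq(0.5, 3.5, by = 1)
  grid <- expand.grid(x = xs, y = ys)
  cells <- rbind(
    data.frame(id = 1:10, type = "AXIAL", x = xs, y = 0),
    data.frame(id = 10 + seq_len(nrow(grid)), type = "PSM",
               x = grid$x, y = grid$y))
  cells$radius <- 0.36
  cells$adhesion_distance <- 0.45

  d <- density_profile(cells, grid_size = 1)
  expect_true(all(d$mean == d$mean[1]))              # flat profile
  expect_true(all(d$region[d$bin < 5] == "pPSM"))
  expect_true(all(d$region[d$bin >= 5] == "aPSM"))
  # binning conserves the total cell count
  expect_equal(sum(d$mean * d$n), nrow(grid))

  # delete half of the pPSM cells: pPSM bands halve, aPSM bands unchanged
  # (extent just under 5 so the deletion region matches the labeled bands)
  set.seed(1)
  cells2 <- delete_ppsm_cells(cells, 0.5, ppsm_extent = 4.9)
  d2 <- density_profile(cells2, grid_size = 1)
  expect_equal(mean(d2$mean[d2$region == "aPSM"]),
               mean(d$mean[d$region == "aPSM"]))
  expect_equal(sum(d2$mean[d2$region == "pPSM"] * d2$n[d2$region == "pPSM"]),
               0.5 * sum(d$mean[d$region == "pPSM"] * d$n[d$region == "pPSM"]))
})

test_that("boundary pressure is zero without motion and tallies PSM wall hits", {
  tc <- tiny_construct()
  tr <- run_simulation(tc, frozen_params(), n_iterations = 20,
                       record_every = 10, seed = 1)
  expect_warning(bp <- boundary_pressure(tr), "empty")
  expect_true(all(bp$mean == 0))

  # active run: PSM cells press on the lateral walls
  tr2 <- run_simulation(build_construct(2, seed = 2), mechanics_params(),
                        n_iterations = 300, record_every = 100, seed = 2)
  bp2 <- boundary_pressure(tr2, from = 0)
  expect_gt(sum(bp2$mean), 0)
  expect_true(all(bp2$mean >= 0))
})

test_that("axial push force is zero when frozen and recorded per iteration", {
  tc <- tiny_construct()
  tr <- run_simulation(tc, frozen_params(), n_iterations = 30,
                       record_every = 10, seed = 1)
  f <- axial_push_force(tr, bin_width = 10, from = 0)
  expect_true(all(abs(f$mean) < 1e-14))
  expect_identical(length(tr$force_series), 30L)
})

test_that("pd_lateral_flux measures ML speeds of PD cells", {
  # hand-built 2-snapshot trajectory: one PD cell moves 0.3 in ML over 1 iter
  mk_snap <- function(iter, y_pd) list(
    iter = iter,
    pos = cbind(c(1, 2, 3, 4, 5), c(0, 0, 0, 0, y_pd)),
    id = 1:5, type = c(rep(0L, 4), 1L))
  traj <- structure(list(
    snapshots = list(mk_snap(0L, 0.1), mk_snap(1L, 0.4)),
    perturbation_iteration = NA_integer_, record_every = 1L,
    n_iterations = 1L), class = "axis_trajectory")
  fx <- pd_lateral_flux(traj, bin_width = 200, halfwidth = 1)
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$mean, 0.3)
  expect_identical(fx$n, 1L)

  # static cells: zero flux
  traj0 <- structure(list(
    snapshots = list(mk_snap(0L, 0.1), mk_snap(1L, 0.1)),
    perturbation_iteration = NA_integer_, record_every = 1L,
    n_iterations = 1L), class = "axis_trajectory")
  expect_equal(pd_lateral_flux(traj0, halfwidth = 1)$mean, 0)
})

test_that("regime classification separates synthetic displacement fields", {
  base <- data.frame(id = 1:20, type = rep(c("AXIAL", "PSM"), 10),
                     x = runif(20, 0, 10), y = runif(20, -4, 4),
                     radius = 0.36, adhesion_distance = 0.45)
  # pure convergence: everyone moves toward the midline
  conv <- base
  conv$y <- conv$y * 0.5
  r1 <- classify_regime(list(base, conv))
  expect_identical(r1$label, "CONVERGENCE")
  expect_lt(r1$ratio, 1)

  # pure elongation: everyone moves posteriorly
  elon <- base
  elon$x <- elon$x + 1
  r2 <- classify_regime(list(base, elon))
  expect_identical(r2$label, "ELONGATION")
  expect_identical(r2$convergence, 0)

  # no displacement: undetermined
  r3 <- classify_regime(list(base, base))
  expect_identical(r3$label, "UNDETERMINED")

  # per-cell labels present
  expect_true(all(r2$cells$dominant %in% c("ELONGATION", "CONVERGENCE",
                                           "TIE")))
})

test_that("replicate aggregation averages per-bin means across tables", {
  t1 <- axisim:::new_timeseries("q", "iteration", 10, c(0, 10), c(1, 3),
                                c(0, 0), c(5L, 5L))
  t2 <- axisim:::new_timeseries("q", "iteration", 10, c(0, 10), c(3, 5),
                                c(0, 0), c(5L, 5L))
  agg <- aggregate_replicates(list(t1, t2))
  expect_equal(agg$mean, c(2, 4))
  expect_equal(agg$sd, c(sqrt(2), sqrt(2)))
  expect_identical(agg$n, c(2L, 2L))
})
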