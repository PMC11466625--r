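test_that("grid generation spans the stated ranges", {
  g <- generate_grid(points_per_axis = 9)
  expect_identical(nrow(g), 9L)
  expect_equal(g$psm_psm, seq(5, 45, by = 5))
  # non-varied parameters at their range midpoints
  expect_equal(g$nc_nc, rep(8.5, 9))
  expect_equal(g$post_post, rep(0.6, 9))
  expect_equal(g$psm_nc, rep(50, 9))
  expect_equal(g$psm_post, rep(35, 9))
  # scaled value of raw 25 is (25 - 5) / 40 = 0.5
  expect_equal(g$scaled_psm_psm[g$psm_psm == 25], 0.5)

  full <- generate_grid(points_per_axis = 3, mode = "full_grid")
  expect_identical(nrow(full), 243L)
  expect_error(generate_grid(points_per_axis = 1), "points_per_axis")
})

test_that("parameter scaling is a bijection over the ranges", {
  r <- sweep_ranges()
  set.seed(1)
  for (p in names(r)) {
    x <- runif(20, r[[p]][1], r[[p]][2])
    names_x <- stats::setNames(x, rep(p, 20))
    sc <- vapply(x, function(v) scale_params(stats::setNames(v, p))[[1]],
                 numeric(1))
    expect_true(all(sc >= 0 & sc <= 1))
    back <- vapply(sc, function(v) unscale_params(stats::setNames(v, p))[[1]],
                   numeric(1))
    expect_equal(back, x, tolerance = 1e-12)
  }
})

fake_slice <- function(labels, scaled = seq(0.1, 0.9, by = 0.2)) {
  d <- data.frame(scaled_psm_psm = rep(scaled, each = length(labels[[1]])),
                  label = unlist(labels))
  attr(d, "vary") <- "psm_psm"
  d
}

test_that("transition detection follows the midpoint rule", {
  # C at 0.1/0.3/0.5, E at 0.7/0.9: midpoint of the bracketing interval
  sl <- fake_slice(list("CONVERGENCE", "CONVERGENCE", "CONVERGENCE",
                        "ELONGATION", "ELONGATION"))
  tr <- find_transition(sl)
  expect_equal(as.numeric(tr), 0.6)
  expect_equal(attr(tr, "interval"), c(0.5, 0.7))
  expect_true(attr(tr, "monotone"))

  # invariant to reversing the slice order
  sl_rev <- sl[rev(seq_len(nrow(sl))), ]
  attr(sl_rev, "vary") <- "psm_psm"
  expect_equal(as.numeric(find_transition(sl_rev)), 0.6)

  # single-regime slice errors
  all_c <- fake_slice(list("CONVERGENCE", "CONVERGENCE", "CONVERGENCE",
                           "CONVERGENCE", "CONVERGENCE"))
  expect_error(find_transition(all_c), "no transition")

  # refining the grid shrinks the bracketing interval
  coarse <- find_transition(fake_slice(
    list("CONVERGENCE", "CONVERGENCE", "ELONGATION"),
    scaled = c(0, 0.5, 1)))
  fine <- find_transition(fake_slice(
    as.list(c(rep("CONVERGENCE", 7), rep("ELONGATION", 2))),
    scaled = seq(0, 1, by = 0.125)))
  expect_lt(diff(attr(fine, "interval")), diff(attr(coarse, "interval")))
})

test_that("non-monotone votes fall back to the isotonic crossing", {
  sl <- fake_slice(list(rep("CONVERGENCE", 5),
                        c(rep("CONVERGENCE", 3), rep("ELONGATION", 2)),
                        c(rep("ELONGATION", 3), rep("CONVERGENCE", 2)),
                        c(rep("CONVERGENCE", 3), rep("ELONGATION", 2)),
                        rep("ELONGATION", 5)))
  expect_warning(tr <- find_transition(sl), "isotonic")
  expect_false(attr(tr, "monotone"))
  expect_gt(as.numeric(tr), 0.3)
  expect_lt(as.numeric(tr), 0.9)
})

test_that("a tiny sweep runs deterministically and records outputs", {
  g <- generate_grid(points_per_axis = 2)
  res <- run_sweep(g, replicates = 2, n_iterations = 30, seed = 5)
  expect_identical(nrow(res), 4L)
  expect_true(all(res$ok))
  expect_true(all(is.finite(res$length)))
  expect_true(all(res$label %in% c("CONVERGENCE", "ELONGATION",
                                   "UNDETERMINED")))
  res2 <- run_sweep(g, replicates = 2, n_iterations = 30, seed = 5)
  expect_identical(res$length, res2$length)
  expect_identical(res$ratio, res2$ratio)
})

planted_sweep <- function(n = 120, seed = 4, noise = 0) {
  set.seed(seed)
  X <- matrix(runif(5 * n), ncol = 5)
  colnames(X) <- paste0("scaled_", names(sweep_ranges()))
  d <- as.data.frame(X)
  # planted linear ground truth
  d$length <- 10 + 8 * X[, 1] - 3 * X[, 2] + 2 * X[, 4] +
    rnorm(n, 0, noise)
  d$width <- 4 - 2 * X[, 1] + X[, 3] + rnorm(n, 0, noise)
  d
}

test_that("surrogate recovers a planted linear map with the 70/15/15 split", {
  d <- planted_sweep(n = 100)
  fit <- fit_surrogate(d, hidden_units = 10, split_seed = 1)
  expect_identical(lengths(fit$split)[["train"]], 70L)
  expect_identical(lengths(fit$split)[["val"]], 15L)
  expect_identical(lengths(fit$split)[["test"]], 15L)
  expect_gt(fit$r2_test, 0.99)

  # predictions come back on the original output scale
  p <- predict(fit, d[1:5, ])
  expect_equal(dim(p), c(5L, 2L))
  expect_lt(max(abs(p[, "length"] - d$length[1:5])), 1)
})

test_that("surrogate finds no signal in permuted targets", {
  d <- planted_sweep(n = 120)
  set.seed(99)
  d$length <- sample(d$length)
  d$width <- sample(d$width)
  fit <- fit_surrogate(d, hidden_units = 10, split_seed = 2)
  expect_lt(fit$r2_test, 0.3)
})

test_that("surrogate input validation", {
  d <- planted_sweep(n = 30)
  expect_error(fit_surrogate(d), "at least 50")
  d2 <- planted_sweep(n = 60)
  d2$length <- 1
  d2$width <- 1
  expect_error(fit_surrogate(d2), "degenerate")
})
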