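test_that("degree-0 intensity fit equals the homogeneous MLE n/|W| exactly", {
  set.seed(42)
  p <- simulate_poisson(NULL, rate = 100 / (pi * 60^2), seed = 42)
  fit <- fit_intensity(p, degree = 0)
  expect_equal(unname(fit$coefficients[["all"]][1]),
               log(p$n / (pi * 60^2)), tolerance = 1e-7)
})

test_that("Berman-Turner quadrature weights sum to the window area within 0.1%", {
  set.seed(2)
  qd <- retinomap:::.bt_quadrature(runif(50, -30, 30), runif(50, -30, 30),
                                   cap_window())
  expect_equal(sum(qd$w), pi * 60^2, tolerance = 1e-3)
})

test_that("log-linear intensity parameters are recovered in simulation", {
  # abbreviated recovery check (the full 200-replicate version runs in the
  # acceptance suite)
  beta <- c(-5.5, 0.02)
  model <- structure(list(degree = 1, levels = "all",
                          coefficients = list(all = c(beta, 0)),
                          window = cap_window()), class = "intensity_model")
  est <- t(vapply(1:30, function(s) {
    p <- simulate_poisson(model, seed = 1000 + s)
    fit_intensity(p, degree = 1)$coefficients[["all"]][1:2]
  }, c(0, 0)))
  expect_equal(colMeans(est), beta, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("log-likelihood is nondecreasing in polynomial degree", {
  set.seed(6)
  p <- simulate_poisson(NULL, rate = 200 / (pi * 60^2), seed = 6)
  lls <- vapply(0:3, function(d) fit_intensity(p, degree = d)$loglik, 0)
  expect_true(all(diff(lls) > -1e-6))
})

test_that("simulation is seeded, respects zero intensity, and hits the Poisson mean", {
  p1 <- simulate_poisson(NULL, rate = 50 / (pi * 60^2), seed = 9)
  p2 <- simulate_poisson(NULL, rate = 50 / (pi * 60^2), seed = 9)
  expect_identical(p1$x, p2$x)
  expect_equal(simulate_poisson(NULL, rate = 0, seed = 1)$n, 0)
  counts <- vapply(1:300, function(s)
    simulate_poisson(NULL, rate = 50 / (pi * 60^2), seed = s)$n, 0L)
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 300))
})

test_that("the K estimator matches its definition for two points", {
  W <- pi * 60^2
  p <- point_pattern(c(-5, 5), c(0, 0))
  k <- k_function(p, r_grid = c(5, 9.999, 10, 20), correction = "none")
  expect_equal(k$k, c(0, 0, W, W))
  expect_true(all(diff(k_function(p, seq(0, 30, 1))$k) >= 0))
  expect_error(k_function(point_pattern(1, 1)), "at least 2")
})

test_that("K detects clustering in a parent-offspring pattern", {
  set.seed(31)
  parents <- simulate_poisson(NULL, rate = 10 / (pi * 60^2), seed = 31)
  ox <- rep(parents$x, each = 15) + rnorm(15 * parents$n, 0, 1.5)
  oy <- rep(parents$y, each = 15) + rnorm(15 * parents$n, 0, 1.5)
  keep <- ox^2 + oy^2 < 59.9^2
  p <- point_pattern(ox[keep], oy[keep])
  k <- k_function(p, r_grid = seq(0, 10, 0.5))
  env <- csr_envelope(p, n_sim = 39, seed = 5, r_grid = k$r)
  expect_true(all(k$k[k$r >= 2 & k$r <= 6] >
                  env$hi[k$r >= 2 & k$r <= 6]))
})

test_that("CSR envelopes are reproducible and degenerate correctly at n_sim = 1", {
  set.seed(3)
  p <- simulate_poisson(NULL, rate = 80 / (pi * 60^2), seed = 3)
  e1 <- csr_envelope(p, n_sim = 1, seed = 7, r_grid = seq(0, 20, 1))
  expect_equal(e1$lo, e1$hi)
  e2 <- csr_envelope(p, n_sim = 19, seed = 8, r_grid = seq(0, 20, 1))
  e3 <- csr_envelope(p, n_sim = 19, seed = 8, r_grid = seq(0, 20, 1))
  expect_identical(e2$lo, e3$lo)
  expect_true(all(e2$lo <= e2$hi))
})

test_that("nearest-neighbour great-circle distances never exceed projected Euclidean", {
  set.seed(17)
  pts <- runif_cap(150)
  q <- project(pts)
  p <- point_pattern(q$x, q$y)
  eu <- nn_distances(p, "projected_euclidean")
  gc <- nn_distances(p, "great_circle")
  expect_true(all(gc <= eu + 1e-9))
  # known pair: (30,0) and (30,90)
  q2 <- project(retinal_point(c(30, 30), c(0, 90)))
  p2 <- point_pattern(q2$x, q2$y)
  expect_equal(nn_distances(p2, "projected_euclidean")[1], 30 * sqrt(2))
  expect_equal(nn_distances(p2, "great_circle")[1], acos(0.75) * 180 / pi)
  expect_error(nn_distances(point_pattern(0, 0)), "at least 2")
})

test_that("permutation p-value follows the add-one formula and is deterministic", {
  set.seed(23)
  ctr <- runif_cap(40)
  eye <- c(rep("m1", 2), rep("m2", 3), paste0("s", 1:35))
  r1 <- within_eye_permutation_test(ctr, eye, B = 99, seed = 4)
  r2 <- within_eye_permutation_test(ctr, eye, B = 99, seed = 4)
  expect_identical(r1$null, r2$null)
  expect_equal(r1$p_value, (1 + sum(r1$null >= r1$observed)) / 100)
  expect_gt(r1$p_value, 0); expect_lte(r1$p_value, 1)
  # widely separated multiplet: small p, consistent with the add-one formula
  # (the null resamples from the full set, so it can occasionally redraw the
  # extreme pair itself)
  far <- retinal_point(c(55, 55, runif(30) * 10), c(0, 180, runif(30) * 360))
  eye2 <- c("m", "m", paste0("s", 1:30))
  rf <- within_eye_permutation_test(far, eye2, B = 999, seed = 1)
  expect_equal(rf$p_value, (1 + sum(rf$null >= rf$observed)) / 1000)
  expect_lt(rf$p_value, 0.02)
  expect_error(within_eye_permutation_test(ctr, paste0("e", 1:40), B = 9),
               "no eye")
  expect_error(within_eye_permutation_test(ctr, eye, B = 0), "B must")
})

test_that("relative density is ~1 under CSR and concentrates mass at co-located points", {
  set.seed(19)
  p <- simulate_poisson(NULL, rate = 2000 / (pi * 60^2), seed = 19)
  rd <- relative_density_map(p, raster_grid(2), bandwidth = 10)
  expect_gt(mean(rd, na.rm = TRUE), 0.9)
  expect_lt(mean(rd, na.rm = TRUE), 1.1)
  # all points in one spot
  p2 <- point_pattern(rep(10, 20), rep(10, 20))
  rd2 <- relative_density_map(p2, raster_grid(2), bandwidth = 5)
  g <- attr(rd2, "grid")
  at <- rd2[which.min(abs(g$y - 10)), which.min(abs(g$x - 10))]
  far <- rd2[which.min(abs(g$y + 40)), which.min(abs(g$x + 30))]
  expect_gt(at, 5)
  expect_lt(far, 1)
  expect_error(relative_density_map(p2, bandwidth = -1), "bandwidth")
})
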