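test_that("perimeter interpolation passes through vertices and recovers a circle", {
  sq <- retinal_point(c(10, 10, 10, 10), c(45, 135, 225, 315))
  dense <- interpolate_perimeter(sq, step = 0.05)
  qv <- project(sq); qd <- project(dense)
  for (i in 1:4) {
    d <- sqrt((qd$x - qv$x[i])^2 + (qd$y - qv$y[i])^2)
    expect_lt(min(d), 1e-6)
  }
  # 24 points on a circle of radius 10 degrees -> curve within 0.1 degree
  circ <- retinomap:::cap_boundary(retinal_point(0, 0), 10, n = 24)
  dense2 <- interpolate_perimeter(circ, step = 0.05)
  r <- sqrt(project(dense2)$x^2 + project(dense2)$y^2)
  expect_lt(max(abs(r - 10)), 0.1)
  expect_error(interpolate_perimeter(retinal_point(c(5, 6), c(0, 10))),
               "at least 3")
})

test_that("interpolated contours exiting the window are clipped to its rim", {
  per <- retinal_point(c(59, 59, 59, 59), c(0, 90, 180, 270))
  dense <- interpolate_perimeter(per, step = 0.1)
  expect_true(all(dense$eccentricity <= 60 + 1e-9))
})

test_that("rasterized cap area converges to the closed form as pitch shrinks", {
  b <- retinomap:::cap_boundary(retinal_point(0, 0), 10, n = 240)
  g <- raster_grid(0.25)
  m <- rasterize(b, g)
  frac <- retinomap:::.mask_area_fraction(m, g)
  expect_equal(frac, cap_fraction(10), tolerance = 0.01)
  gc_ <- raster_grid(0.5); gf <- raster_grid(0.125)
  ec <- abs(retinomap:::.mask_area_fraction(rasterize(b, gc_), gc_) -
            cap_fraction(10))
  ef <- abs(retinomap:::.mask_area_fraction(rasterize(b, gf), gf) -
            cap_fraction(10))
  expect_gt(ec, ef)
})

test_that("the window boundary rasterizes to every in-window pixel", {
  b <- retinal_point(rep(60, 720), seq(0, 359.5, by = 0.5))
  g <- raster_grid(1)
  m <- rasterize(b, g)
  expect_true(all(m[g$inside]))
})

test_that("tumor metrics fill centroid and area and respect reflection invariance", {
  rec <- cap_record(0, 0, 30)
  rec <- compute_tumor_metrics(rec)
  expect_equal(rec$area_fraction, cap_fraction(30), tolerance = 5e-3)
  expect_lt(rec$centroid$eccentricity, 0.1)
  # idempotent
  rec2 <- compute_tumor_metrics(rec)
  expect_equal(rec2$area_fraction, rec$area_fraction)
  # mirror image has identical metrics
  rec3 <- cap_record(25, 70, 8)
  rec3m <- list(perimeter = canonicalize(rec3$perimeter, "left"))
  m1 <- compute_tumor_metrics(rec3)
  m2 <- compute_tumor_metrics(rec3m)
  expect_equal(m1$area_fraction, m2$area_fraction, tolerance = 1e-9)
  expect_equal(m2$centroid$polar_angle, (360 - m1$centroid$polar_angle) %% 360,
               tolerance = 1e-6)
  # centroid of a convex region lies inside it
  q <- project(interpolate_perimeter(rec3$perimeter))
  cq <- project(m1$centroid)
  expect_true(mgcv::in.out(as.matrix(rbind(q, q[1, ])),
                           matrix(c(cq$x, cq$y), 1)))
})

test_that("cumulative burden counts distinct eyes, not tumors", {
  g <- raster_grid(1)
  t1 <- cap_record(10, 0, 8, eye_id = "A")
  t2 <- cap_record(10, 30, 8, eye_id = "B")
  one <- cumulative_burden(list(t1), g)
  expect_equal(max(one), 1L)
  expect_equal(sum(one == 1), sum(rasterize(
    interpolate_perimeter(t1$perimeter, 0.25), g)))
  two <- cumulative_burden(list(t1, t2), g)
  expect_equal(max(two), 2L)
  expect_true(any(two == 2) && any(two == 1))
  # same eye: overlapping tumors count once
  t2b <- cap_record(10, 30, 8, eye_id = "A")
  same <- cumulative_burden(list(t1, t2b), g)
  expect_equal(max(same), 1L)
})

test_that("quartile-fraction burden lies in [0,1] and peaks where tumors overlap", {
  g <- raster_grid(1)
  tums <- list(cap_record(10, 0, 10, eye_id = "A", age_quartile = 1),
               cap_record(12, 20, 10, eye_id = "B", age_quartile = 1),
               cap_record(40, 180, 6, eye_id = "C", age_quartile = 3))
  qb <- cumulative_burden(tums, g, "quartile_fraction")
  expect_true(all(vapply(qb, function(m) all(m >= 0 & m <= 1), TRUE)))
  expect_equal(max(qb$Q1), 1)   # the two Q1 caps overlap near the fovea
  expect_equal(max(qb$Q2), 0)
})

test_that("margin and centroid distances follow cap geometry", {
  a <- cap_record(20, 0, 5)
  b <- cap_record(50, 0, 5)
  md <- margin_distance(a, b)
  expect_equal(md$centroid_distance, 30, tolerance = 0.1)
  expect_equal(md$margin, 20, tolerance = 0.2)
  expect_false(md$overlap)
  expect_lte(md$margin, md$centroid_distance)
  # tangent caps: margin ~0, no overlap
  t1 <- cap_record(20, 0, 5); t2 <- cap_record(30, 0, 5)
  mt <- margin_distance(t1, t2)
  expect_lt(mt$margin, 0.3)
  # nested caps: overlap, margin 0
  n1 <- cap_record(20, 0, 12); n2 <- cap_record(20, 0, 3)
  mn <- margin_distance(n1, n2)
  expect_true(mn$overlap)
  expect_equal(mn$margin, 0)
  # disjoint circular caps: margin = centroid distance - r1 - r2
  expect_equal(md$margin, md$centroid_distance - 5 - 5, tolerance = 0.2)
})
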