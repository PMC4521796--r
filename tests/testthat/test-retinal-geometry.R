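test_that("azimuthal equidistant projection fixes the origin and preserves radial distance", {
  expect_equal(unlist(project(retinal_point(0, 0))), c(x = 0, y = 0))
  q <- project(retinal_point(30, 90))
  expect_equal(q$x, 30)
  expect_equal(q$y, 0, tolerance = 1e-12)
  q2 <- project(retinal_point(30, 0))
  expect_equal(c(q2$x, q2$y), c(0, 30), tolerance = 1e-12)
  expect_equal(sqrt((q$x - q2$x)^2 + (q$y - q2$y)^2), 30 * sqrt(2))
  # |project(p)| = eccentricity for arbitrary points
  set.seed(11)
  p <- retinal_point(runif(500, 0, 60), runif(500, 0, 360))
  pr <- project(p)
  expect_equal(sqrt(pr$x^2 + pr$y^2), p$eccentricity, tolerance = 1e-12)
})

test_that("unproject inverts project to numerical tolerance and rejects out-of-window points", {
  expect_equal(unproject(data.frame(x = 0, y = 0))$eccentricity, 0)
  expect_equal(unproject(data.frame(x = 30, y = 0))$polar_angle, 90)
  set.seed(7)
  p <- retinal_point(runif(1000, 0, 60), runif(1000, 0, 360))
  rt <- unproject(project(p))
  expect_lt(max(abs(rt$eccentricity - p$eccentricity)), 1e-9)
  dth <- abs(rt$polar_angle - p$polar_angle)
  expect_lt(max(pmin(dth, 360 - dth)), 1e-9)
  expect_error(unproject(data.frame(x = 59, y = 59)), "outside")
})

test_that("great-circle distance matches the dot-product oracle and pole geometry", {
  for (phi in c(0, 45, 123, 300))
    expect_equal(great_circle_distance(retinal_point(0, 0),
                                       retinal_point(30, phi)), 30)
  expect_equal(great_circle_distance(retinal_point(30, 0),
                                     retinal_point(30, 180)), 60)
  expect_equal(great_circle_distance(retinal_point(30, 0),
                                     retinal_point(30, 90)),
               acos(cos(pi / 6)^2 + sin(pi / 6)^2 * cos(pi / 2)) * 180 / pi)
  # symmetry and triangle inequality on random triples
  set.seed(21)
  a <- runif_cap(200); b <- runif_cap(200); c <- runif_cap(200)
  expect_equal(great_circle_distance(a, b), great_circle_distance(b, a))
  expect_true(all(great_circle_distance(a, c) <=
                  great_circle_distance(a, b) + great_circle_distance(b, c) + 1e-9))
})

test_that("projected Euclidean distance dominates the great-circle distance", {
  set.seed(13)
  a <- runif_cap(2000); b <- runif_cap(2000)
  gc <- great_circle_distance(a, b)
  qa <- project(a); qb <- project(b)
  eu <- sqrt((qa$x - qb$x)^2 + (qa$y - qb$y)^2)
  expect_true(all(gc <= eu + 1e-9))
  # equality when one point is the fovea
  f <- retinal_point(rep(0, 50), 0)
  b2 <- runif_cap(50)
  expect_equal(great_circle_distance(f, b2),
               sqrt(project(b2)$x^2 + project(b2)$y^2), tolerance = 1e-9)
})

test_that("left-eye canonicalization reflects across the vertical meridian", {
  expect_equal(canonicalize(retinal_point(20, 30), "left")$polar_angle, 330)
  expect_equal(canonicalize(retinal_point(20, 0), "left")$polar_angle, 0)
  expect_equal(canonicalize(retinal_point(20, 30), "right")$polar_angle, 30)
  # involution
  p <- retinal_point(c(10, 20, 55), c(15, 181, 359.5))
  twice <- canonicalize(canonicalize(p, "left"), "left")
  expect_equal(twice$polar_angle, p$polar_angle)
  expect_equal(twice$eccentricity, p$eccentricity)
})

test_that("spherical region area recovers closed-form cap fractions", {
  full <- retinal_point(rep(60, 360), seq(0, 359))
  expect_equal(spherical_region_area(full)$fraction, 1, tolerance = 1e-4)
  b30 <- retinal_point(rep(30, 360), seq(0, 359))
  expect_equal(spherical_region_area(b30)$fraction, cap_fraction(30),
               tolerance = 1e-4)
  # off-center cap, small
  off <- retinomap:::cap_boundary(retinal_point(35, 200), 8, n = 240)
  expect_equal(spherical_region_area(off)$fraction, cap_fraction(8),
               tolerance = 1e-3)
  expect_error(spherical_region_area(retinal_point(c(1, 2), c(0, 0))),
               "at least 3")
})

test_that("irregular polygon area agrees with a Monte-Carlo rejection oracle", {
  set.seed(5)
  per <- generate_tumor_perimeter(retinal_point(18, 120), 0.08,
                                  irregularity = 0.35, seed = 42)
  bnd <- interpolate_perimeter(per)
  got <- spherical_region_area(bnd)$fraction
  # oracle: uniform points on the 60-degree cap, even-odd membership in the
  # projected polygon
  set.seed(99)
  pts <- runif_cap(200000)
  q <- project(pts)
  inb <- mgcv::in.out(as.matrix(rbind(project(bnd), project(bnd)[1, ])),
                      as.matrix(q))
  expect_equal(got, mean(inb), tolerance = 0.02)
})

test_that("region area is invariant under reflection and rotation about the foveal axis", {
  set.seed(8)
  per <- generate_tumor_perimeter(retinal_point(25, 70), 0.06,
                                  irregularity = 0.3, seed = 17)
  a0 <- spherical_region_area(per)$fraction
  refl <- canonicalize(per, "left")
  expect_equal(spherical_region_area(refl)$fraction, a0, tolerance = 1e-9)
  rot <- retinal_point(per$eccentricity, (per$polar_angle + 137) %% 360)
  expect_equal(spherical_region_area(rot)$fraction, a0, tolerance = 1e-9)
})

test_that("spherical centroid matches symmetry and a Monte-Carlo mean-direction oracle", {
  cc <- retinomap:::cap_boundary(retinal_point(20, 45), 12, n = 240)
  ctr <- spherical_centroid(cc)
  expect_equal(ctr$eccentricity, 20, tolerance = 1e-3)
  expect_equal(ctr$polar_angle, 45, tolerance = 1e-3)
  full <- spherical_centroid(retinal_point(rep(60, 360), seq(0, 359)))
  expect_lt(full$eccentricity, 1e-3)
  # crescent: cap minus offset cap, approximated by a boundary walk; use an
  # irregular generated region and compare against rejection-sampled mean
  per <- generate_tumor_perimeter(retinal_point(30, 260), 0.10,
                                  irregularity = 0.4, seed = 31)
  bnd <- interpolate_perimeter(per)
  got <- spherical_centroid(bnd)
  set.seed(12)
  pts <- runif_cap(400000)
  q <- project(pts)
  inb <- mgcv::in.out(as.matrix(rbind(project(bnd), project(bnd)[1, ])),
                      as.matrix(q))
  u <- retinomap:::.unit_vectors(pts[inb, ])
  m <- colMeans(u); m <- m / sqrt(sum(m^2))
  mc <- retinomap:::.vectors_to_points(matrix(m, 1))
  expect_lt(great_circle_distance(got, mc), 0.2)
})

test_that("perimeter-mode centroid of a symmetric cap matches the area centroid", {
  cc <- retinomap:::cap_boundary(retinal_point(25, 300), 10, n = 240)
  pa <- spherical_centroid(cc, "area")
  pp <- spherical_centroid(cc, "perimeter")
  expect_lt(great_circle_distance(pa, pp), 0.2)
})

test_that("maximum centroid eccentricity behaves at endpoints and between modes", {
  expect_equal(max_centroid_eccentricity(1, "approx"), 0)
  expect_equal(max_centroid_eccentricity(1, "exact"), 0, tolerance = 1e-9)
  expect_equal(max_centroid_eccentricity(0, "approx"), 60)
  expect_equal(max_centroid_eccentricity(0, "exact"), 60)
  expect_equal(max_centroid_eccentricity(0.25, "approx"), 30)
  expect_equal(max_centroid_eccentricity(0.25, "exact"),
               60 - acos(0.875) * 180 / pi, tolerance = 1e-9)
  a <- seq(0, 1, by = 0.001)
  ap <- max_centroid_eccentricity(a, "approx")
  ex <- max_centroid_eccentricity(a, "exact")
  expect_true(all(diff(ap) <= 0) && all(diff(ex) <= 1e-9))
  expect_lt(max(abs(ap - ex)), 2)
  expect_error(max_centroid_eccentricity(1.2), "\\[0, 1\\]")
})
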