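# Internal angle helpers: degrees externally, radians internally.
.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Retinal point in polar coordinates
#'
#' A location on the retina given by eccentricity (angular distance from the
#' fovea, degrees) and polar angle (degrees clockwise from the superior
#' vertical meridian in canonical right-eye orientation, so that 90 degrees
#' points nasally).
#'
#' @param eccentricity numeric vector of eccentricities in degrees, in
#'   \code{[0, 60]} for points inside the standard mapped window.
#' @param polar_angle numeric vector of polar angles in degrees; normalized to
#'   \code{[0, 360)}. At eccentricity 0 the polar angle is stored as 0.
#' @return a data.frame of class \code{retinal_point} with columns
#'   \code{eccentricity} and \code{polar_angle}.
#' @examples
#' retinal_point(30, 90)
#' @export
retinal_point <- function(eccentricity, polar_angle) {
  stopifnot(is.numeric(eccentricity), is.numeric(polar_angle))
  n <- max(length(eccentricity), length(polar_angle))
  eccentricity <- rep_len(as.numeric(eccentricity), n)
  polar_angle <- rep_len(as.numeric(polar_angle), n)
  if (any(!is.finite(eccentricity)) || any(!is.finite(polar_angle)))
    stop("non-finite retinal coordinates")
  if (any(eccentricity < 0))
    stop("eccentricity must be nonnegative")
  polar_angle <- polar_angle %% 360
  polar_angle[eccentricity == 0] <- 0
  out <- data.frame(eccentricity = eccentricity, polar_angle = polar_angle)
  class(out) <- c("retinal_point", "data.frame")
  out
}

#' Circular cap observation window
#'
#' The mapped retina is modeled as a spherical cap of given angular radius
#' about the fovea; in the azimuthal equidistant projection it is a disc of
#' the same radius (degrees). The optic disc lands near polar angle 88 degrees
#' in canonical right-eye orientation.
#'
#' @param radius maximum eccentricity in degrees (default 60).
#' @param optic_disc_polar_angle polar angle of the optic disc marker, degrees.
#' @return an object of class \code{cap_window} with fields \code{radius},
#'   \code{optic_disc_polar_angle}, planar \code{area} (square degrees,
#'   \eqn{\pi r^2}) and spherical \code{solid_angle} (steradians).
#' @export
cap_window <- function(radius = 60, optic_disc_polar_angle = 88) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(
    radius = radius,
    optic_disc_polar_angle = optic_disc_polar_angle,
    area = pi * radius^2,
    solid_angle = 2 * pi * (1 - cos(.deg2rad(radius)))
  ), class = "cap_window")
}

#' @export
print.cap_window <- function(x, ...) {
  cat(sprintf("cap window: radius %g deg, planar area %.1f deg^2\n",
              x$radius, x$area))
  invisible(x)
}

#' Azimuthal equidistant projection of retinal points
#'
#' Projects retinal polar coordinates onto the plane so that distance and
#' direction from the fovea are preserved: \code{x = ecc * sin(theta)},
#' \code{y = ecc * cos(theta)}. Superior is +y and nasal is +x for a
#' canonical right eye.
#'
#' @param p a \code{retinal_point} (or data.frame with \code{eccentricity},
#'   \code{polar_angle}).
#' @return data.frame with columns \code{x}, \code{y} in degrees.
#' @examples
#' project(retinal_point(30, 90))  # lands on the +x (nasal) axis
#' @export
project <- function(p) {
  th <- .deg2rad(p$polar_angle)
  data.frame(x = p$eccentricity * sin(th), y = p$eccentricity * cos(th))
}

#' Inverse azimuthal equidistant projection
#'
#' @param q data.frame with planar coordinates \code{x}, \code{y} in degrees.
#' @param window a \code{cap_window}; points outside it are an error.
#' @return a \code{retinal_point}.
#' @export
unproject <- function(q, window = cap_window()) {
  r <- sqrt(q$x^2 + q$y^2)
  if (any(r > window$radius + 1e-9))
    stop("point outside the mapped window")
  th <- .rad2deg(atan2(q$x, q$y)) %% 360
  retinal_point(r, ifelse(r == 0, 0, th))
}

# Unit vectors on the retinal sphere: fovea at the pole (colatitude =
# eccentricity), polar angle as longitude. Column matrix n x 3.
.unit_vectors <- function(p) {
  e <- .deg2rad(p$eccentricity)
  th <- .deg2rad(p$polar_angle)
  cbind(sin(e) * sin(th), sin(e) * cos(th), cos(e))
}

.vectors_to_points <- function(u) {
  u <- u / sqrt(rowSums(u^2))
  ecc <- .rad2deg(acos(pmin(1, pmax(-1, u[, 3]))))
  th <- .rad2deg(atan2(u[, 1], u[, 2])) %% 360
  retinal_point(ecc, ifelse(ecc == 0, 0, th))
}

#' Great-circle distance between retinal points
#'
#' Angular distance in degrees along the retinal sphere, with the fovea as
#' pole: \eqn{d = \arccos(u \cdot v)} for the corresponding unit vectors.
#' Always less than or equal to the Euclidean distance between the points'
#' azimuthal equidistant projections.
#'
#' @param a,b \code{retinal_point}s (vectorized elementwise).
#' @return numeric vector of distances in degrees.
#' @examples
#' great_circle_distance(retinal_point(30, 0), retinal_point(30, 90))
#' @export
great_circle_distance <- function(a, b) {
  ua <- .unit_vectors(a)
  ub <- .unit_vectors(b)
  d <- rowSums(ua * ub)
  .rad2deg(acos(pmin(1, pmax(-1, d))))
}

# Full pairwise great-circle distance matrix (degrees) for one point set.
# (pmin/pmax keep the first argument's attributes, so the matrix goes first)
.gc_dist_matrix <- function(p) {
  u <- .unit_vectors(p)
  g <- tcrossprod(u)
  .rad2deg(acos(pmax(pmin(g, 1), -1)))
}

#' Canonicalize a retinal point to right-eye orientation
#'
#' Right-eye points are unchanged; left-eye points are reflected across the
#' vertical meridian (superior/inferior preserved, nasal/temporal swapped):
#' polar angle maps to \code{(360 - polar_angle) \%\% 360}. Pooling left and
#' right eyes this way aligns nasal retina with nasal retina.
#'
#' @param p a \code{retinal_point}.
#' @param side \code{"left"} or \code{"right"} (recycled).
#' @return a \code{retinal_point} in canonical right-eye orientation.
#' @export
canonicalize <- function(p, side) {
  side <- match.arg(side, c("left", "right"), several.ok = TRUE)
  side <- rep_len(side, nrow(p))
  th <- ifelse(side == "left", (360 - p$polar_angle) %% 360, p$polar_angle)
  retinal_point(p$eccentricity, th)
}

# Densify a closed spherical polygon: slerp along great-circle edges so that
# consecutive vertices are at most `step` degrees apart. Input/output n x 3
# unit-vector matrices; the polygon is implicitly closed.
.densify_boundary <- function(u, step = 0.5) {
  n <- nrow(u)
  nxt <- c(2:n, 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- u[i, ]; b <- u[nxt[i], ]
    ang <- acos(min(1, max(-1, sum(a * b))))
    if (ang < 1e-12) { out[[i]] <- matrix(a, 1); next }
    k <- max(1L, ceiling(.rad2deg(ang) / step))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    s <- sin(ang)
    out[[i]] <- outer(sin((1 - t) * ang) / s, a) + outer(sin(t * ang) / s, b)
  }
  do.call(rbind, out)
}

# Signed solid angle of a closed boundary (unit-vector rows, assumed densified)
# via the line integral  A = \oint (1 - cos eccentricity) d(longitude),
# exact for the retinal-pole parameterization by Stokes' theorem.
.signed_solid_angle <- function(u) {
  ecc <- acos(pmin(1, pmax(-1, u[, 3])))
  th <- atan2(u[, 1], u[, 2])
  nxt <- c(2:nrow(u), 1)
  dth <- th[nxt] - th
  dth <- ((dth + pi) %% (2 * pi)) - pi          # wrap to (-pi, pi]
  cm <- 1 - cos((ecc + ecc[nxt]) / 2)
  sum(cm * dth)
}

# Unnormalized spherical area centroid vector: m = 1/2 \oint u x du, the
# surface integral of position over the enclosed region. Orientation must be
# counterclockwise (positive signed area).
.centroid_vector <- function(u) {
  nxt <- c(2:nrow(u), 1)
  v <- u[nxt, , drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  colSums(cr) / 2
}

.check_boundary <- function(boundary) {
  if (nrow(boundary) < 3)
    stop("boundary needs at least 3 vertices")
  u <- .unit_vectors(boundary)
  keep <- c(TRUE, rowSums((u[-1, , drop = FALSE] -
                           u[-nrow(u), , drop = FALSE])^2) > 1e-20)
  u <- u[keep, , drop = FALSE]
  if (sum(sqrt(rowSums((u - u[c(2:nrow(u), 1), , drop = FALSE])^2)) > 1e-10) < 3 ||
      nrow(u) < 3)
    stop("degenerate boundary: fewer than 3 distinct vertices")
  u
}

#' Area of a spherical region on the retina
#'
#' Solid angle of the region enclosed by an ordered closed boundary of
#' retinal points, with great-circle edges densified to small arc steps, and
#' the same area expressed as a fraction of the mapped window (the 60-degree
#' cap by default). Computed on the sphere, not in the flat projection.
#'
#' @param boundary a \code{retinal_point} data.frame of ordered vertices
#'   (closed implicitly; at least 3 distinct vertices).
#' @param window a \code{cap_window}.
#' @param step densification step along edges, degrees of arc.
#' @return list with \code{solid_angle} (steradians) and \code{fraction}
#'   (of the window cap area).
#' @examples
#' # a 30-degree cap about the fovea covers (1-cos30)/(1-cos60) of the window
#' b <- retinal_point(rep(30, 72), seq(0, 355, by = 5))
#' spherical_region_area(b)$fraction
#' @export
spherical_region_area <- function(boundary, window = cap_window(), step = 0.5) {
  u <- .check_boundary(boundary)
  ud <- .densify_boundary(u, step)
  sa <- .signed_solid_angle(ud)
  solid <- abs(sa)
  cap <- 2 * pi * (1 - cos(.deg2rad(window$radius)))
  if (solid <= 0 || solid > 4 * pi)
    stop("geometry error: ill-formed boundary")
  list(solid_angle = solid, fraction = solid / cap)
}

#' Spherical centroid of a retinal region
#'
#' Center of mass of the enclosed area under uniform surface density: the
#' normalized mean of unit vectors over the region, evaluated by the exact
#' boundary integral \eqn{m = \frac12 \oint u \times du} and projected back
#' to the sphere. \code{mode = "perimeter"} instead averages the densified
#' boundary points with arc-length weights (contour center of mass).
#'
#' @inheritParams spherical_region_area
#' @param mode \code{"area"} (default) or \code{"perimeter"}.
#' @return a single \code{retinal_point}.
#' @export
spherical_centroid <- function(boundary, mode = c("area", "perimeter"),
                               step = 0.5) {
  mode <- match.arg(mode)
  u <- .check_boundary(boundary)
  ud <- .densify_boundary(u, step)
  if (mode == "area") {
    # polar angle runs clockwise (superior -> nasal), so a boundary with
    # positive theta-integral area is clockwise for the cross-product
    # integral; orient it the other way round
    if (.signed_solid_angle(ud) > 0)
      ud <- ud[rev(seq_len(nrow(ud))), , drop = FALSE]
    m <- .centroid_vector(ud)
  } else {
    nxt <- c(2:nrow(ud), 1)
    seg <- sqrt(rowSums((ud[nxt, , drop = FALSE] - ud)^2))
    w <- (seg + seg[c(nrow(ud), 1:(nrow(ud) - 1))]) / 2
    m <- colSums(ud * w)
  }
  nm <- sqrt(sum(m^2))
  if (nm < 1e-9)
    stop("degenerate centroid: mean direction vector has near-zero norm")
  .vectors_to_points(matrix(m / nm, 1))
}

#' Maximum centroid eccentricity for a tumor of given area
#'
#' A circular tumor that just touches the edge of the mapped window
#' constrains how far out its center can sit. The approximate rule treats
#' area as scaling with the square of planar radius,
#' \eqn{60 (1 - \sqrt{a})}; the exact rule inverts the spherical cap-area
#' formula, returning \eqn{60 - \rho} with
#' \eqn{(1-\cos\rho)/(1-\cos 60^\circ) = a}.
#'
#' @param area_fraction tumor area as a fraction of the mapped window, in
#'   \code{[0, 1]} (vectorized).
#' @param mode \code{"approx"} or \code{"exact"}.
#' @param window a \code{cap_window}.
#' @return maximum centroid eccentricity in degrees.
#' @examples
#' max_centroid_eccentricity(0.25)            # 30
#' max_centroid_eccentricity(0.25, "exact")   # ~31.04
#' @export
max_centroid_eccentricity <- function(area_fraction, mode = c("approx", "exact"),
                                      window = cap_window()) {
  mode <- match.arg(mode)
  if (any(!is.finite(area_fraction)) || any(area_fraction < 0) ||
      any(area_fraction > 1))
    stop("area_fraction must lie in [0, 1]")
  R <- window$radius
  if (mode == "approx") {
    R * (1 - sqrt(area_fraction))
  } else {
    capR <- 1 - cos(.deg2rad(R))
    rho <- .rad2deg(acos(pmin(1, pmax(-1, 1 - area_fraction * capR))))
    R - rho
  }
}

# Boundary of a circular cap of geodesic radius rho (deg) about a retinal
# center, as n retinal points. Exact on the sphere (rotated small circle).
cap_boundary <- function(center, rho, n = 180) {
  c0 <- .unit_vectors(center)[1, ]
  # local orthonormal frame at the center
  a <- if (abs(c0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- a - sum(a * c0) * c0
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(c0[2] * e1[3] - c0[3] * e1[2],
          c0[3] * e1[1] - c0[1] * e1[3],
          c0[1] * e1[2] - c0[2] * e1[1])
  phi <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rr <- .deg2rad(rho)
  u <- cos(rr) * matrix(c0, n, 3, byrow = TRUE) +
    sin(rr) * (outer(cos(phi), e1) + outer(sin(phi), e2))
  .vectors_to_points(u)
}
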