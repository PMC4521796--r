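#' Raster grid over the projected window
#'
#' Square pixel grid covering the azimuthal equidistant projection of the
#' mapped window; pixels whose centers fall outside the window disc are
#' masked. The default 0.25-degree pitch gives map fidelity comparable to the
#' hand-digitized maps the workflow emulates.
#'
#' @param pitch pixel size in degrees (> 0).
#' @param window a \code{cap_window}.
#' @return object of class \code{raster_grid}: vectors \code{x}, \code{y} of
#'   pixel-center coordinates, logical matrix \code{inside} (rows = y,
#'   cols = x), and the pitch/window.
#' @export
raster_grid <- function(pitch = 0.25, window = cap_window()) {
  stopifnot(pitch > 0)
  R <- window$radius
  ctr <- seq(-R + pitch / 2, R - pitch / 2, by = pitch)
  inside <- outer(ctr^2, ctr^2, "+") <= R^2   # rows index y, cols index x
  structure(list(x = ctr, y = ctr, inside = inside, pitch = pitch,
                 window = window), class = "raster_grid")
}

# Spherical surface area element of each pixel row (same for all columns):
# a planar pixel at radius r in the azimuthal equidistant projection covers
# spherical area pitch^2 * sinc(r), with r in radians.
.pixel_spherical_weight <- function(grid) {
  r <- .deg2rad(sqrt(outer(grid$y^2, grid$x^2, "+")))
  w <- ifelse(r < 1e-12, 1, sin(r) / r)
  .deg2rad(grid$pitch)^2 * w
}

#' Smoothly interpolate a tumor perimeter
#'
#' Closed periodic cubic spline through the measured perimeter vertices in
#' projected coordinates, parameterized by cumulative chord length and
#' resampled at a target spacing. The curve passes through every input
#' vertex; points that exit the window are clipped radially to its boundary.
#'
#' @param perimeter a \code{retinal_point} data.frame of ordered vertices
#'   (at least 3).
#' @param step target spacing between resampled points, degrees.
#' @param window a \code{cap_window}.
#' @return a \code{retinal_point} data.frame of densified boundary points
#'   (closed implicitly).
#' @export
interpolate_perimeter <- function(perimeter, step = 0.25,
                                  window = cap_window()) {
  if (nrow(perimeter) < 3)
    stop("perimeter needs at least 3 vertices")
  stopifnot(step > 0)
  q <- project(perimeter)
  # drop a duplicated closing vertex if present
  n <- nrow(q)
  if (sqrt((q$x[1] - q$x[n])^2 + (q$y[1] - q$y[n])^2) < 1e-9)
    q <- q[-n, , drop = FALSE]
  if (nrow(q) < 3) stop("perimeter needs at least 3 distinct vertices")
  xs <- c(q$x, q$x[1]); ys <- c(q$y, q$y[1])
  d <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  if (d[length(d)] <= 0) stop("degenerate perimeter: zero length")
  m <- max(16L, ceiling(d[length(d)] / step))
  t_out <- seq(0, d[length(d)], length.out = m + 1L)[-(m + 1L)]
  px <- stats::spline(d, xs, method = "periodic", xout = t_out)$y
  py <- stats::spline(d, ys, method = "periodic", xout = t_out)$y
  r <- sqrt(px^2 + py^2)
  out <- r > window$radius
  if (any(out)) {                      # radial clip to the window rim
    sc <- window$radius / r[out]
    px[out] <- px[out] * sc
    py[out] <- py[out] * sc
  }
  if (.polygon_self_intersects(px, py))
    warning("interpolated contour self-intersects; even-odd fill applies")
  unproject(data.frame(x = px, y = py), window)
}

# Cheap self-intersection screen on a closed polyline: bounding-box prefilter
# then segment pair test. O(n^2) over coarse subsampling to stay fast.
.polygon_self_intersects <- function(x, y, max_check = 120L) {
  n <- length(x)
  if (n > max_check) {
    idx <- unique(round(seq(1, n, length.out = max_check)))
    x <- x[idx]; y <- y[idx]; n <- length(x)
  }
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]
    a1x <- x[i]; a1y <- y[i]; a2x <- x2[i]; a2y <- y2[i]
    d1x <- a2x - a1x; d1y <- a2y - a1y
    s1 <- d1x * (y[js] - a1y) - d1y * (x[js] - a1x)
    s2 <- d1x * (y2[js] - a1y) - d1y * (x2[js] - a1x)
    d2x <- x2[js] - x[js]; d2y <- y2[js] - y[js]
    s3 <- d2x * (a1y - y[js]) - d2y * (a1x - x[js])
    s4 <- d2x * (a2y - y[js]) - d2y * (a2x - x[js])
    if (any(s1 * s2 < 0 & s3 * s4 < 0)) return(TRUE)
  }
  FALSE
}

#' Rasterize a closed boundary onto a grid
#'
#' Pixels whose centers lie on or within the boundary (even-odd rule) are
#' labeled tumor. The spherical area of labeled pixels converges to the
#' exact spherical region area as the pitch shrinks.
#'
#' @param boundary a \code{retinal_point} data.frame (closed implicitly),
#'   e.g. from \code{\link{interpolate_perimeter}}.
#' @param grid a \code{raster_grid}.
#' @return logical matrix (rows = y, cols = x) masked to the window; attribute
#'   \code{empty} flags a tumor smaller than one pixel.
#' @export
rasterize <- function(boundary, grid = raster_grid()) {
  q <- project(boundary)
  keepx <- which(grid$x >= min(q$x) - grid$pitch & grid$x <= max(q$x) + grid$pitch)
  keepy <- which(grid$y >= min(q$y) - grid$pitch & grid$y <= max(q$y) + grid$pitch)
  mask <- matrix(FALSE, length(grid$y), length(grid$x))
  if (length(keepx) && length(keepy)) {
    pts <- cbind(rep(grid$x[keepx], each = length(keepy)),
                 rep(grid$y[keepy], times = length(keepx)))
    inb <- mgcv::in.out(as.matrix(rbind(q, q[1, ])), pts)
    mask[keepy, keepx] <- matrix(inb, length(keepy), length(keepx))
  }
  mask <- mask & grid$inside
  if (!any(mask))
    attr(mask, "empty") <- TRUE
  mask
}

# Spherical area fraction of a pixel mask.
.mask_area_fraction <- function(mask, grid) {
  w <- .pixel_spherical_weight(grid)
  sum(w[mask]) / grid$window$solid_angle
}

#' Fill derived metrics of a tumor record
#'
#' Computes the spherical centroid and area fraction from the (canonical)
#' perimeter and assigns them to the record. Idempotent.
#'
#' @param record a list-like tumor record with element \code{perimeter}
#'   (a \code{retinal_point} data.frame).
#' @param window a \code{cap_window}.
#' @param step densification step for the spherical integrals, degrees.
#' @return the record with \code{centroid} (a \code{retinal_point}) and
#'   \code{area_fraction} filled.
#' @export
compute_tumor_metrics <- function(record, window = cap_window(), step = 0.5) {
  b <- interpolate_perimeter(record$perimeter, step = 0.25, window = window)
  record$area_fraction <- spherical_region_area(b, window, step)$fraction
  record$centroid <- spherical_centroid(b, "area", step)
  record
}

#' Cumulative tumor burden map
#'
#' In \code{eye_count} mode, the per-pixel number of distinct eyes with tumor
#' at that location (multiple tumors in one eye count once). In
#' \code{quartile_fraction} mode, per age quartile, the fraction of that
#' quartile's tumors overlapping each pixel.
#'
#' @param tumors list of tumor records, each with \code{perimeter} (canonical
#'   right-eye orientation), \code{eye_id}, and (for quartile mode)
#'   \code{age_quartile}.
#' @param grid a \code{raster_grid}.
#' @param mode \code{"eye_count"} or \code{"quartile_fraction"}.
#' @return for \code{eye_count}: an integer matrix; for
#'   \code{quartile_fraction}: a list of 4 fraction matrices. Both carry the
#'   grid as attribute \code{grid}.
#' @export
cumulative_burden <- function(tumors, grid = raster_grid(),
                              mode = c("eye_count", "quartile_fraction")) {
  mode <- match.arg(mode)
  dims <- dim(grid$inside)
  masks <- lapply(tumors, function(tr)
    rasterize(interpolate_perimeter(tr$perimeter, step = 0.25,
                                    window = grid$window), grid))
  if (mode == "eye_count") {
    out <- matrix(0L, dims[1], dims[2])
    if (length(tumors)) {
      eyes <- vapply(tumors, function(tr) as.character(tr$eye_id), "")
      for (e in unique(eyes)) {
        eye_mask <- Reduce(`|`, masks[eyes == e])
        out <- out + eye_mask
      }
    }
  } else {
    qs <- vapply(tumors, function(tr) as.integer(tr$age_quartile), 1L)
    out <- lapply(1:4, function(q) {
      sel <- which(qs == q)
      if (!length(sel)) return(matrix(0, dims[1], dims[2]))
      Reduce(`+`, masks[sel]) / length(sel)
    })
    names(out) <- paste0("Q", 1:4)
  }
  attr(out, "grid") <- grid
  out
}

#' Margin and centroid distances between two tumors
#'
#' The margin is the shortest great-circle distance between the tumor
#' boundaries (zero when the regions touch or overlap); the centroid distance
#' is the great-circle distance between the spherical centroids.
#'
#' @param a,b tumor records with \code{perimeter} (and optionally cached
#'   \code{centroid}).
#' @param window a \code{cap_window}.
#' @param step boundary densification step, degrees (resolution of the margin
#'   estimate).
#' @return list with \code{margin}, \code{centroid_distance} (degrees) and
#'   logical \code{overlap}.
#' @export
margin_distance <- function(a, b, window = cap_window(), step = 0.25) {
  ba <- interpolate_perimeter(a$perimeter, step = step, window = window)
  bb <- interpolate_perimeter(b$perimeter, step = step, window = window)
  ca <- if (!is.null(a$centroid)) a$centroid else spherical_centroid(ba)
  cb <- if (!is.null(b$centroid)) b$centroid else spherical_centroid(bb)
  cd <- great_circle_distance(ca, cb)
  qa <- project(ba); qb <- project(bb)
  a_in_b <- any(mgcv::in.out(as.matrix(rbind(qb, qb[1, ])), as.matrix(qa)))
  b_in_a <- any(mgcv::in.out(as.matrix(rbind(qa, qa[1, ])), as.matrix(qb)))
  ua <- .unit_vectors(ba); ub <- .unit_vectors(bb)
  dmin <- .rad2deg(acos(min(1, max(-1, max(ua %*% t(ub))))))
  overlap <- a_in_b || b_in_a
  margin <- if (overlap) 0 else dmin
  list(margin = margin, centroid_distance = cd, overlap = overlap)
}
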