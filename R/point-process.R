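#' Marked point pattern in the projected window
#'
#' Tumor centroids as points in the azimuthal equidistant projection, with
#' optional per-point marks (mutation, age quartile, area quartile, eye id),
#' observed in a circular cap window.
#'
#' @param x,y point coordinates in degrees (projection plane).
#' @param marks optional data.frame with one row per point (e.g. columns
#'   \code{mutation}, \code{age_quartile}, \code{area_quartile},
#'   \code{eye_id}).
#' @param window a \code{cap_window}.
#' @return object of class \code{point_pattern}.
#' @export
point_pattern <- function(x, y, marks = NULL, window = cap_window()) {
  stopifnot(length(x) == length(y))
  if (any(x^2 + y^2 > window$radius^2 + 1e-9))
    stop("points outside the window")
  if (!is.null(marks)) {
    marks <- as.data.frame(marks)
    if (nrow(marks) != length(x)) stop("marks must match points in length")
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), marks = marks,
                 window = window, n = length(x)), class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points in a %g-degree circular window\n",
              x$n, x$window$radius))
  if (!is.null(x$marks))
    cat("marks:", paste(names(x$marks), collapse = ", "), "\n")
  invisible(x)
}

# Monomial design matrix in (x, y) up to total degree d, columns named.
.poly_design <- function(x, y, degree) {
  stopifnot(degree >= 0)
  cols <- list(); nms <- character(0)
  for (d in 0:degree) for (i in 0:d) {
    j <- d - i
    cols[[length(cols) + 1L]] <- x^i * y^j
    nms <- c(nms, if (d == 0) "1" else paste0(
      if (i > 0) paste0("x", if (i > 1) i else "") else "",
      if (j > 0) paste0("y", if (j > 1) j else "") else ""))
  }
  m <- do.call(cbind, cols)
  colnames(m) <- nms
  m
}

# Berman-Turner quadrature scheme: dummy grid over the window plus the data
# points; counting-measure weights (cell area / points in cell) so weights
# sum to the window area. Cell areas account for the disc boundary by
# subgrid integration.
.bt_quadrature <- function(x, y, window, dummy = 32L) {
  R <- window$radius
  pitch <- 2 * R / dummy
  ctr <- seq(-R + pitch / 2, R - pitch / 2, by = pitch)
  dx <- rep(ctr, each = dummy); dy <- rep(ctr, times = dummy)
  # fraction of each cell inside the disc, 12x12 subsamples per cell
  sub <- (seq_len(12) - 0.5) / 12 - 0.5
  frac <- vapply(seq_along(dx), function(i) {
    sx <- dx[i] + sub * pitch
    sy <- dy[i] + sub * pitch
    mean(outer(sx^2, sy^2, "+") <= R^2)
  }, 0)
  keep <- frac > 0
  dx <- dx[keep]; dy <- dy[keep]
  cell_area <- frac[keep] * pitch^2
  # normalize so the quadrature measure has exactly the window's mass
  cell_area <- cell_area * (pi * R^2) / sum(cell_area)
  qx <- c(x, dx); qy <- c(y, dy)
  is_data <- c(rep(TRUE, length(x)), rep(FALSE, length(dx)))
  # assign every quadrature point to its cell
  ix <- pmin(dummy - 1L, pmax(0L, floor((qx + R) / pitch)))
  iy <- pmin(dummy - 1L, pmax(0L, floor((qy + R) / pitch)))
  cell <- ix * dummy + iy
  dummy_cell <- cell[!is_data]
  counts <- table(cell)
  area_of <- numeric(dummy * dummy)
  area_of[dummy_cell + 1L] <- cell_area
  w <- area_of[cell + 1L] / as.numeric(counts[as.character(cell)])
  list(x = qx, y = qy, w = w, is_data = is_data)
}

#' Fit an inhomogeneous Poisson intensity model
#'
#' Maximizes the inhomogeneous Poisson point-process log-likelihood
#' \eqn{\sum_i \log\lambda(x_i) - \int_W \lambda} for a log-polynomial
#' intensity \eqn{\log\lambda(x,y) = \sum \beta \, x^i y^j}, via the
#' Berman-Turner quadrature device: dummy points plus data points with
#' counting-measure weights summing to the window area, fitted as a weighted
#' log-linear Poisson regression. With a mark formula, independent
#' intensities are fitted per mark level (valid for Poisson processes by the
#' marking theorem).
#'
#' @param pattern a \code{point_pattern}.
#' @param degree polynomial degree (>= 0) of the log-intensity.
#' @param mark_formula optional name of a mark column; one intensity surface
#'   is fitted per level of that mark.
#' @param dummy dummy-grid resolution per axis (default 32).
#' @return object of class \code{intensity_model} with \code{coefficients}
#'   (per mark level), \code{loglik}, \code{aic}, \code{degree},
#'   \code{window}, and the quadrature used.
#' @examples
#' set.seed(1)
#' p <- simulate_poisson(NULL, rate = 100 / (pi * 60^2), seed = 1)
#' fit_intensity(p, degree = 0)$coefficients[[1]]  # ~ log(n / area)
#' @export
fit_intensity <- function(pattern, degree = 2, mark_formula = NULL,
                          dummy = 32L) {
  if (degree < 0) stop("degree must be >= 0")
  ncoef <- (degree + 1) * (degree + 2) / 2
  if (pattern$n < ncoef)
    stop("fewer points than coefficients")
  levels_of <- "all"
  if (!is.null(mark_formula)) {
    if (is.null(pattern$marks) || is.null(pattern$marks[[mark_formula]]))
      stop("mark column not found: ", mark_formula)
    levels_of <- as.character(sort(unique(pattern$marks[[mark_formula]])))
  }
  fits <- list(); ll <- 0
  for (lev in levels_of) {
    sel <- if (lev == "all" && is.null(mark_formula)) rep(TRUE, pattern$n)
           else pattern$marks[[mark_formula]] == lev
    qd <- .bt_quadrature(pattern$x[sel], pattern$y[sel], pattern$window, dummy)
    X <- .poly_design(qd$x, qd$y, degree)
    yy <- ifelse(qd$is_data, 1 / qd$w, 0)
    fit <- suppressWarnings(stats::glm.fit(X, yy, weights = qd$w,
                                           family = stats::poisson()))
    if (!fit$converged)
      stop("intensity fit did not converge (", fit$iter, " iterations)")
    beta <- fit$coefficients
    names(beta) <- colnames(X)
    lam <- exp(drop(X %*% beta))
    ll_lev <- sum(log(lam[qd$is_data])) - sum(qd$w * lam)
    fits[[lev]] <- list(beta = beta, loglik = ll_lev, quad = qd)
    ll <- ll + ll_lev
  }
  k <- ncoef * length(levels_of)
  structure(list(coefficients = lapply(fits, `[[`, "beta"),
                 loglik = ll, aic = -2 * ll + 2 * k, degree = degree,
                 mark_formula = mark_formula, window = pattern$window,
                 levels = levels_of, fits = fits),
            class = "intensity_model")
}

#' @export
print.intensity_model <- function(x, ...) {
  cat(sprintf(
    "inhomogeneous Poisson intensity, degree %d; logLik %.2f, AIC %.2f\n",
    x$degree, x$loglik, x$aic))
  invisible(x)
}

#' Evaluate a fitted intensity surface
#'
#' @param model an \code{intensity_model}.
#' @param x,y coordinates (degrees) at which to evaluate.
#' @param level mark level (default the first).
#' @return intensity values (points per square degree).
#' @export
predict_intensity <- function(model, x, y, level = NULL) {
  if (is.null(level)) level <- model$levels[1]
  beta <- model$coefficients[[level]]
  X <- .poly_design(x, y, model$degree)
  exp(drop(X %*% beta))
}

#' Simulate an inhomogeneous Poisson pattern in the cap window
#'
#' Thinning of a homogeneous Poisson proposal at an upper bound of the
#' intensity (evaluated on a fine grid with a safety margin). With
#' \code{model = NULL} and a \code{rate}, simulates homogeneous (CSR)
#' patterns directly.
#'
#' @param model an \code{intensity_model}, or \code{NULL} for CSR.
#' @param window a \code{cap_window} (taken from the model when present).
#' @param seed integer seed; same seed gives the identical pattern.
#' @param rate homogeneous intensity (points per square degree) when
#'   \code{model} is NULL.
#' @param level mark level of the model to simulate from.
#' @return a \code{point_pattern}.
#' @export
simulate_poisson <- function(model, window = cap_window(), seed = NULL,
                             rate = NULL, level = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(model)) window <- model$window
  R <- window$radius
  if (is.null(model)) {
    if (is.null(rate) || rate < 0) stop("need a nonnegative rate for CSR")
    lam_max <- rate
  } else {
    g <- seq(-R, R, length.out = 201)
    gx <- rep(g, each = 201); gy <- rep(g, times = 201)
    ok <- gx^2 + gy^2 <= R^2
    lam <- predict_intensity(model, gx[ok], gy[ok], level)
    if (any(!is.finite(lam))) stop("intensity unbounded on the window")
    lam_max <- max(lam) * 1.05
  }
  n_prop <- stats::rpois(1, lam_max * window$area)
  if (n_prop == 0) return(point_pattern(numeric(0), numeric(0), window = window))
  rr <- R * sqrt(stats::runif(n_prop))
  th <- stats::runif(n_prop, 0, 2 * pi)
  px <- rr * sin(th); py <- rr * cos(th)
  if (!is.null(model)) {
    keep <- stats::runif(n_prop) < predict_intensity(model, px, py, level) / lam_max
    px <- px[keep]; py <- py[keep]
  }
  point_pattern(px, py, window = window)
}

# Area of intersection of two discs of radius R whose centers are d apart.
.disc_overlap_area <- function(d, R) {
  d <- pmin(d, 2 * R)
  2 * R^2 * acos(d / (2 * R)) - (d / 2) * sqrt(pmax(0, 4 * R^2 - d^2))
}

#' Ripley's K function with CSR reference
#'
#' Empirical K: \eqn{\hat K(r) = \frac{|W|}{n(n-1)} \sum_{i \ne j} e_{ij}
#' 1[d_{ij} \le r]}, using Euclidean distance in the projection. The
#' translation edge correction uses \eqn{e_{ij} = |W| / |W \cap W_{d_{ij}}|}
#' for the circular window. The CSR reference \eqn{\pi r^2} is attached.
#'
#' @param pattern a \code{point_pattern} with at least 2 points.
#' @param r_grid distances (degrees) at which to evaluate; default 0..30.
#' @param correction \code{"none"} or \code{"translation"}.
#' @return object of class \code{k_result}: \code{r}, \code{k}, \code{theo}
#'   (\eqn{\pi r^2}), plus envelope columns once \code{\link{csr_envelope}}
#'   has been attached.
#' @export
k_function <- function(pattern, r_grid = seq(0, 30, by = 0.5),
                       correction = c("translation", "none")) {
  correction <- match.arg(correction)
  n <- pattern$n
  if (n < 2) stop("need at least 2 points")
  W <- pattern$window$area
  R <- pattern$window$radius
  dmat <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
  d <- dmat[upper.tri(dmat)]
  e <- if (correction == "translation") W / .disc_overlap_area(d, R) else rep(1, length(d))
  k <- vapply(r_grid, function(r) sum(e[d <= r]), 0)
  k <- 2 * k * W / (n * (n - 1))      # each unordered pair counted twice
  structure(list(r = r_grid, k = k, theo = pi * r_grid^2,
                 correction = correction, n = n, window = pattern$window),
            class = "k_result")
}

#' Pointwise CSR envelope for a summary statistic
#'
#' Simulates \code{n_sim} CSR (binomial, same n) patterns in the pattern's
#' window, computes the statistic on the same r grid, and returns pointwise
#' rank envelopes (the \code{rank}-th smallest/largest simulated value at
#' each r).
#'
#' @param pattern a \code{point_pattern}.
#' @param statistic a function (pattern, r_grid) -> numeric; default the K
#'   function with the pattern's correction choice.
#' @param n_sim number of simulations (default 99).
#' @param seed integer seed.
#' @param r_grid evaluation distances.
#' @param rank which extreme to take (1 = min/max envelopes).
#' @return list with \code{r}, \code{lo}, \code{hi}, \code{n_sim},
#'   \code{rank}, \code{seed}.
#' @export
csr_envelope <- function(pattern, statistic = NULL, n_sim = 99, seed = 1,
                         r_grid = seq(0, 30, by = 0.5), rank = 1) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (is.null(statistic))
    statistic <- function(p, r) k_function(p, r)$k
  set.seed(seed)
  R <- pattern$window$radius
  sims <- matrix(0, n_sim, length(r_grid))
  for (s in seq_len(n_sim)) {
    rr <- R * sqrt(stats::runif(pattern$n))
    th <- stats::runif(pattern$n, 0, 2 * pi)
    p <- point_pattern(rr * sin(th), rr * cos(th), window = pattern$window)
    sims[s, ] <- statistic(p, r_grid)
  }
  lo <- apply(sims, 2, function(v) sort(v)[rank])
  hi <- apply(sims, 2, function(v) sort(v, decreasing = TRUE)[rank])
  list(r = r_grid, lo = lo, hi = hi, n_sim = n_sim, rank = rank, seed = seed)
}

#' Nearest-neighbour distances in two geometries
#'
#' Per-point distance to the nearest other point, either Euclidean in the
#' azimuthal equidistant projection or great-circle on the retinal sphere.
#' The great-circle distance never exceeds the projected Euclidean distance
#' for the same pair.
#'
#' @param pattern a \code{point_pattern} (n >= 2).
#' @param metric \code{"projected_euclidean"} or \code{"great_circle"}.
#' @return numeric vector of nearest-neighbour distances, degrees.
#' @export
nn_distances <- function(pattern,
                         metric = c("projected_euclidean", "great_circle")) {
  metric <- match.arg(metric)
  if (pattern$n < 2) stop("need at least 2 points")
  if (metric == "projected_euclidean") {
    dmat <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
  } else {
    p <- unproject(data.frame(x = pattern$x, y = pattern$y), pattern$window)
    dmat <- .gc_dist_matrix(p)
  }
  diag(dmat) <- Inf
  unname(apply(dmat, 1, min))
}

#' Within-eye tumor separation permutation test
#'
#' Tests whether multiple tumors within an eye are further apart than
#' comparable groups sampled from the full set of tumor centroids. The
#' observed statistic is the mean within-eye nearest-neighbour great-circle
#' distance over all eyes with two or more tumors; each null draw samples
#' centroids from the full pattern (without replacement) into groups
#' matching the observed multiplet-size multiset and recomputes the
#' statistic. One-sided p for observed greater than null,
#' \eqn{p = (1 + \#\{null \ge obs\}) / (1 + B)}.
#'
#' @param centroids a \code{retinal_point} data.frame of all tumor centroids
#'   (canonical orientation).
#' @param eye_id vector of eye identifiers, one per centroid.
#' @param B number of permutation draws (>= 1).
#' @param seed integer seed.
#' @param replace sample null groups with replacement (default FALSE).
#' @return object of class \code{permutation_result}: \code{observed},
#'   \code{null} (length B), \code{p_value}, \code{B}, \code{seed},
#'   \code{multiplet_sizes}.
#' @export
within_eye_permutation_test <- function(centroids, eye_id, B = 999, seed = 1,
                                        replace = FALSE) {
  if (B < 1) stop("B must be >= 1")
  eye_id <- as.character(eye_id)
  stopifnot(length(eye_id) == nrow(centroids))
  sizes <- table(eye_id)
  multi <- names(sizes)[sizes >= 2]
  if (!length(multi)) stop("no eye has 2 or more tumors")
  dmat <- .gc_dist_matrix(centroids)
  diag(dmat) <- Inf
  group_stat <- function(idx_list) {
    v <- unlist(lapply(idx_list, function(ix) {
      sub <- dmat[ix, ix, drop = FALSE]
      apply(sub, 1, min)
    }))
    mean(v)
  }
  obs <- group_stat(split(seq_along(eye_id), eye_id)[multi])
  msz <- as.integer(sizes[multi])
  ntot <- nrow(centroids)
  if (!replace && sum(msz) > ntot)
    stop("multiplet sizes exceed available centroids for sampling without replacement")
  set.seed(seed)
  null <- vapply(seq_len(B), function(b) {
    picked <- sample.int(ntot, sum(msz), replace = replace)
    group_stat(split(picked, rep(seq_along(msz), msz)))
  }, 0)
  p <- (1 + sum(null >= obs)) / (1 + B)
  structure(list(observed = obs, null = null, p_value = p, B = B, seed = seed,
                 multiplet_sizes = msz), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "within-eye separation: observed %.2f deg, B = %d, one-sided p = %.4g\n",
    x$observed, x$B, x$p_value))
  invisible(x)
}

#' Relative tumor-centroid density map
#'
#' Gaussian kernel intensity estimate in the projection, renormalized for
#' window edge mass, divided by the CSR-expected uniform density n/|W|.
#' Values above 1 flag locations with more centroids than expected under
#' complete spatial randomness of the same number of tumors.
#'
#' @param pattern a \code{point_pattern} (n >= 1).
#' @param grid a \code{raster_grid} for evaluation (coarser pitch is fine).
#' @param bandwidth Gaussian kernel standard deviation, degrees (> 0).
#' @return matrix of density ratios (NA outside the window), grid attached as
#'   attribute \code{grid}.
#' @export
relative_density_map <- function(pattern, grid = raster_grid(pitch = 1),
                                 bandwidth = 10) {
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (pattern$n < 1) stop("need at least 1 point")
  gx <- grid$x; gy <- grid$y
  # raw kernel sum on the grid: for each point, separable Gaussian
  dens <- matrix(0, length(gy), length(gx))
  for (i in seq_len(pattern$n)) {
    kx <- stats::dnorm(gx, pattern$x[i], bandwidth)
    ky <- stats::dnorm(gy, pattern$y[i], bandwidth)
    dens <- dens + outer(ky, kx)
  }
  # edge renormalization: kernel mass inside the window at each location,
  # computed by blurring the window mask with the same kernel
  pitch <- grid$pitch
  half <- ceiling(4 * bandwidth / pitch)
  kern <- stats::dnorm(seq(-half, half) * pitch, 0, bandwidth) * pitch
  blur1 <- function(m) {
    t(apply(m, 1, function(row)
      stats::filter(c(rep(0, half), row, rep(0, half)), kern,
                    sides = 2)[(half + 1):(half + length(row))]))
  }
  mask_num <- grid$inside * 1
  edge <- blur1(t(blur1(t(mask_num))))
  edge[edge < 1e-10] <- NA
  ratio <- (dens / edge) / (pattern$n / grid$window$area)
  ratio[!grid$inside] <- NA
  attr(ratio, "grid") <- grid
  ratio
}
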