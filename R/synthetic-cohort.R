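#' Configuration for the synthetic retinoblastoma cohort generator
#'
#' Defaults encode the cohort structure the analysis assumes: 67 mapped
#' patients of whom 39 are bilateral (all bilateral patients carry germline
#' RB1 mutations) and 43 germline in total; only 24 of 39 bilateral patients
#' contribute a mapped fellow eye, giving ~91 mapped eyes; germline eyes
#' carry Poisson-distributed extra tumors at rate 38/67 so the cohort
#' averages ~129 mapped tumors. Ages are per-mutation lognormal (medians
#' 7.9 and 21.6 months, clipped to the observed ranges). Tumor-centroid
#' density per age quartile is a mixture of isotropic Gaussian kernels in
#' the projection whose default centers follow the reported age-quartile
#' clusters (macula + superonasal periphery; inferotemporal posterior pole;
#' inferonasal quadrant; nasal + superotemporal periphery); the cluster
#' effect sizes are plausible stand-ins, not fitted values. Tumor area
#' decreases with age quartile and eccentricity. Small fundoscopy-only
#' tumors are anterior-biased with a superior-to-inferior shift across age
#' quartiles.
#'
#' @param n_patients number of patients.
#' @param bilateral_fraction fraction of patients with bilateral disease.
#' @param germline_fraction fraction of patients with germline mutations
#'   (must be >= bilateral fraction; bilateral implies germline).
#' @param fellow_eye_mapped_prob probability a bilateral patient's fellow
#'   eye is mapped.
#' @param age_model per-mutation list: \code{median} (months), \code{sdlog},
#'   \code{range} for clipped lognormal ages.
#' @param quartile_kernels per-age-quartile data.frame of Gaussian kernel
#'   \code{x}, \code{y} centers (projected degrees), \code{weight}, \code{sd}.
#' @param area_base median area fraction per age quartile (decreasing).
#' @param area_sdlog lognormal spread of area fractions.
#' @param area_ecc_rate exponential decay of area with centroid eccentricity
#'   (per degree).
#' @param extra_tumor_rate Poisson rate of additional tumors per germline eye.
#' @param min_separation within-eye minimum great-circle separation between
#'   tumor centroids, degrees (repulsion); set 0 to disable.
#' @param irregularity radial perimeter noise amplitude (0 = circular caps).
#' @param n_vertices measured perimeter vertices per tumor.
#' @param small_tumor_rate expected fundoscopy-only small tumors per
#'   bilateral patient.
#' @param small_anterior_prob,small_meridian_prob,small_nasal_prob sector
#'   probabilities for small tumors.
#' @param small_inferior_prob P(inferior | not meridian) per age quartile.
#' @param detection_area_cutoff drop generated tumors below this area
#'   fraction (0 = keep all).
#' @param window a \code{cap_window}.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 67,
                          bilateral_fraction = 39 / 67,
                          germline_fraction = 43 / 67,
                          fellow_eye_mapped_prob = 24 / 39,
                          age_model = list(
                            germline = list(median = 7.9, sdlog = 0.9,
                                            range = c(0.4, 108.3)),
                            somatic = list(median = 21.6, sdlog = 0.7,
                                           range = c(1.4, 77.5))),
                          quartile_kernels = NULL,
                          area_base = c(0.055, 0.04, 0.028, 0.018),
                          area_sdlog = 0.6,
                          area_ecc_rate = 0.015,
                          extra_tumor_rate = 38 / 67,
                          min_separation = 40,
                          irregularity = 0.25,
                          n_vertices = 24,
                          small_tumor_rate = 50 / 39,
                          small_anterior_prob = 42 / 50,
                          small_meridian_prob = 9 / 50,
                          small_nasal_prob = 0.55,
                          small_inferior_prob = c(0.3, 0.42, 0.55, 0.68),
                          detection_area_cutoff = 0,
                          window = cap_window()) {
  if (germline_fraction < bilateral_fraction)
    stop("bilateral patients are all germline; germline fraction too small")
  if (is.null(quartile_kernels)) {
    quartile_kernels <- list(
      # Q1: macula + superonasal periphery
      data.frame(x = c(0, 31.8), y = c(0, 31.8),
                 weight = c(0.6, 0.4), sd = c(8, 9)),
      # Q2: inferotemporal quadrant of the posterior pole
      data.frame(x = -10.6, y = -10.6, weight = 1, sd = 8),
      # Q3: inferonasal quadrant
      data.frame(x = 14.1, y = -14.1, weight = 1, sd = 9),
      # Q4: nasal + superotemporal periphery, more diffuse
      data.frame(x = c(40, -31.8), y = c(0, 31.8),
                 weight = c(0.5, 0.5), sd = c(12, 12)))
  }
  cfg <- list(n_patients = n_patients, bilateral_fraction = bilateral_fraction,
              germline_fraction = germline_fraction,
              fellow_eye_mapped_prob = fellow_eye_mapped_prob,
              age_model = age_model, quartile_kernels = quartile_kernels,
              area_base = area_base, area_sdlog = area_sdlog,
              area_ecc_rate = area_ecc_rate,
              extra_tumor_rate = extra_tumor_rate,
              min_separation = min_separation,
              irregularity = irregularity, n_vertices = n_vertices,
              small_tumor_rate = small_tumor_rate,
              small_anterior_prob = small_anterior_prob,
              small_meridian_prob = small_meridian_prob,
              small_nasal_prob = small_nasal_prob,
              small_inferior_prob = small_inferior_prob,
              detection_area_cutoff = detection_area_cutoff,
              window = window)
  class(cfg) <- "cohort_config"
  cfg
}

.rtrunc_lnorm <- function(n, median, sdlog, range) {
  ml <- log(median)
  plo <- stats::plnorm(range[1], ml, sdlog)
  phi <- stats::plnorm(range[2], ml, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), ml, sdlog)
}

# Maximum feasible area fraction for a circular tumor centered at ecc.
.max_area_at_ecc <- function(ecc, window = cap_window()) {
  rho <- window$radius - ecc
  (1 - cos(.deg2rad(rho))) / (1 - cos(.deg2rad(window$radius)))
}

#' Generate a star-shaped tumor perimeter around a centroid
#'
#' Builds a closed boundary at geodesic distance \eqn{\rho(\phi)} from the
#' requested centroid, with smooth periodic radial noise scaled by
#' \code{irregularity} (0 gives a circular cap). The base radius is
#' calibrated so the realized spherical area is within 5 percent of the
#' request. The tumor must fit the window: centroid eccentricity may not
#' exceed \code{max_centroid_eccentricity(area_fraction, "exact")}.
#'
#' @param centroid a single \code{retinal_point}.
#' @param area_fraction requested area as a fraction of the mapped window.
#' @param irregularity radial noise amplitude (>= 0; about 0.3 gives
#'   naturalistic lobed outlines).
#' @param n_vertices number of perimeter vertices to emit.
#' @param seed integer seed (optional; uses the current RNG state if NULL).
#' @param window a \code{cap_window}.
#' @return a \code{retinal_point} data.frame of ordered perimeter vertices.
#' @export
generate_tumor_perimeter <- function(centroid, area_fraction,
                                     irregularity = 0, n_vertices = 24,
                                     seed = NULL, window = cap_window()) {
  if (!is.null(seed)) set.seed(seed)
  if (area_fraction <= 0 || area_fraction > 1)
    stop("area_fraction must be in (0, 1]")
  emax <- max_centroid_eccentricity(area_fraction, "exact", window)
  if (centroid$eccentricity[1] > emax + 1e-9)
    stop(sprintf(
      "infeasible placement: centroid eccentricity %.1f exceeds %.1f for area %.3f",
      centroid$eccentricity[1], emax, area_fraction))
  phi <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  shape <- rep(1, n_vertices)
  if (irregularity > 0) {
    g <- rep(0, n_vertices)
    for (h in 1:3)
      g <- g + stats::rnorm(1, 0, 0.6 / h) * cos(h * phi) +
               stats::rnorm(1, 0, 0.6 / h) * sin(h * phi)
    shape <- pmax(0.25, 1 + irregularity * g)
  }
  cap <- 1 - cos(.deg2rad(window$radius))
  rho0 <- .rad2deg(acos(1 - area_fraction * cap))
  c0 <- .unit_vectors(centroid)[1, ]
  a <- if (abs(c0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- a - sum(a * c0) * c0; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(c0[2] * e1[3] - c0[3] * e1[2],
          c0[3] * e1[1] - c0[1] * e1[3],
          c0[1] * e1[2] - c0[2] * e1[1])
  room <- window$radius - centroid$eccentricity[1]
  make <- function(rho_deg) {
    rho_deg <- pmin(rho_deg, room - 1e-3)
    rr <- .deg2rad(rho_deg)
    cos(rr) * matrix(c0, n_vertices, 3, byrow = TRUE) +
      sin(rr) * (cos(phi) * matrix(e1, n_vertices, 3, byrow = TRUE) +
                 sin(phi) * matrix(e2, n_vertices, 3, byrow = TRUE))
  }
  scale <- 1
  target <- area_fraction * cap * 2 * pi
  for (it in 1:6) {
    u <- make(rho0 * shape * scale)
    got <- abs(.signed_solid_angle(.densify_boundary(u, 0.5)))
    if (abs(got / target - 1) < 0.02) break
    scale <- scale * sqrt(target / got)
  }
  .vectors_to_points(u)
}

#' Generate a synthetic retinoblastoma cohort
#'
#' Draws a full cohort (patients, eyes, mapped tumors with marks and
#' perimeters, fundoscopy-only sector records) from a
#' \code{\link{cohort_config}}, reproducibly for a given seed. Bilateral
#' patients are always germline. Age quartiles and tumor-area quartiles are
#' recomputed per cohort, so their boundaries are emergent.
#'
#' @param config a \code{cohort_config}.
#' @param seed integer seed; sub-streams are derived by fixed offsets.
#' @param detail \code{"full"} synthesizes perimeters and recomputes derived
#'   metrics from them; \code{"centroids"} skips perimeter synthesis (the
#'   sampled centroid and area stand in as the derived values), for
#'   inexpensive large-replicate studies of centroid-level statistics.
#' @return object of class \code{rb_cohort}: data.frames \code{patients},
#'   \code{eyes}, \code{sectors}, a list \code{tumors} of per-tumor records,
#'   and the config/seed.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            detail = c("full", "centroids")) {
  detail <- match.arg(detail)
  stopifnot(inherits(config, "cohort_config"))
  window <- config$window
  set.seed(seed)

  n <- config$n_patients
  n_bilat <- round(n * config$bilateral_fraction)
  n_germ <- max(n_bilat, round(n * config$germline_fraction))
  laterality <- c(rep("bilateral", n_bilat), rep("unilateral", n - n_bilat))
  mutation <- rep("somatic", n)
  mutation[seq_len(n_bilat)] <- "germline"
  if (n_germ > n_bilat && n > n_bilat)
    mutation[n_bilat + sample.int(n - n_bilat, n_germ - n_bilat)] <- "germline"
  age <- numeric(n)
  for (m in c("germline", "somatic")) {
    am <- config$age_model[[m]]
    idx <- which(mutation == m)
    age[idx] <- .rtrunc_lnorm(length(idx), am$median, am$sdlog, am$range)
  }
  qs <- quartile_split(age)
  patients <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                         laterality = laterality, mutation = mutation,
                         age_months = age, age_quartile = qs$quartile,
                         stringsAsFactors = FALSE)

  # eyes: every patient contributes one mapped eye; bilateral patients a
  # second with the configured probability
  first_side <- sample(c("left", "right"), n, replace = TRUE)
  eyes <- data.frame(patient_id = patients$patient_id, side = first_side,
                     stringsAsFactors = FALSE)
  fellow <- which(laterality == "bilateral" &
                  stats::runif(n) < config$fellow_eye_mapped_prob)
  if (length(fellow))
    eyes <- rbind(eyes, data.frame(
      patient_id = patients$patient_id[fellow],
      side = ifelse(first_side[fellow] == "left", "right", "left"),
      stringsAsFactors = FALSE))
  eyes$eye_id <- paste0(eyes$patient_id, "_", substr(eyes$side, 1, 1))
  icrb_p <- c(A = 3, B = 29, C = 18, D = 32, E = 9) / 91
  eyes$icrb_group <- sample(names(icrb_p), nrow(eyes), TRUE, icrb_p)

  # tumors per eye
  mut_of <- stats::setNames(patients$mutation, patients$patient_id)
  qrt_of <- stats::setNames(patients$age_quartile, patients$patient_id)
  age_of <- stats::setNames(patients$age_months, patients$patient_id)
  n_tum <- 1L + ifelse(mut_of[eyes$patient_id] == "germline",
                       stats::rpois(nrow(eyes), config$extra_tumor_rate), 0L)

  sample_centroid <- function(q, placed_u) {
    kern <- config$quartile_kernels[[q]]
    best <- NULL; best_sep <- -Inf
    for (try in 1:200) {
      ki <- sample.int(nrow(kern), 1, prob = kern$weight)
      cx <- stats::rnorm(1, kern$x[ki], kern$sd[ki])
      cy <- stats::rnorm(1, kern$y[ki], kern$sd[ki])
      if (cx^2 + cy^2 > (window$radius - 2)^2) next
      p <- unproject(data.frame(x = cx, y = cy), window)
      u <- .unit_vectors(p)[1, ]
      sep <- if (is.null(placed_u)) Inf else
        min(.rad2deg(acos(pmin(1, pmax(-1, placed_u %*% u)))))
      if (sep >= config$min_separation) return(p)
      if (sep > best_sep) { best_sep <- sep; best <- p }
    }
    best
  }

  tumors <- list(); tid <- 0L
  for (ei in seq_len(nrow(eyes))) {
    pid <- eyes$patient_id[ei]
    q <- qrt_of[[pid]]
    placed_u <- NULL
    for (k in seq_len(n_tum[ei])) {
      ctr <- sample_centroid(q, placed_u)
      if (is.null(ctr)) next
      placed_u <- rbind(placed_u, .unit_vectors(ctr))
      ecc <- ctr$eccentricity
      med_area <- config$area_base[q] * exp(-config$area_ecc_rate * ecc)
      af <- stats::rlnorm(1, log(med_area), config$area_sdlog)
      af <- min(af, 0.9 * .max_area_at_ecc(ecc, window))
      af <- max(af, 5e-4)
      if (af < config$detection_area_cutoff) next
      tid <- tid + 1L
      rec <- list(patient_id = pid, eye_id = eyes$eye_id[ei],
                  tumor_id = sprintf("T%04d", tid), side = eyes$side[ei],
                  mutation = mut_of[[pid]], age_months = age_of[[pid]],
                  icrb_group = eyes$icrb_group[ei], age_quartile = q,
                  centroid = ctr, area_fraction = af)
      if (detail == "full") {
        # perimeter drawn in canonical orientation, then stored as measured
        # in the eye's own orientation
        per <- generate_tumor_perimeter(ctr, af, config$irregularity,
                                        config$n_vertices, seed = NULL,
                                        window = window)
        rec$perimeter <- canonicalize(per, rec$side)  # involution: undo below
        rec$perimeter_canonical <- per
        rec <- compute_tumor_metrics_from(rec, window)
      }
      tumors[[tid]] <- rec
    }
  }

  # area quartiles over the realized cohort
  if (length(tumors)) {
    afs <- vapply(tumors, `[[`, 0, "area_fraction")
    aq <- quartile_split(afs)$quartile
    for (i in seq_along(tumors)) tumors[[i]]$area_quartile <- aq[i]
  }

  # fundoscopy-only small tumors for bilateral patients
  bilat <- patients[patients$laterality == "bilateral", ]
  n_small <- stats::rpois(nrow(bilat), config$small_tumor_rate)
  sectors <- NULL
  if (sum(n_small) > 0) {
    sp <- rep(seq_len(nrow(bilat)), n_small)
    q <- bilat$age_quartile[sp]
    vertical <- ifelse(stats::runif(length(sp)) < config$small_meridian_prob,
                       "meridian",
                       ifelse(stats::runif(length(sp)) <
                                config$small_inferior_prob[q],
                              "inferior", "superior"))
    sectors <- data.frame(
      patient_id = bilat$patient_id[sp],
      age_quartile = q,
      vertical = vertical,
      horizontal = ifelse(stats::runif(length(sp)) < config$small_nasal_prob,
                          "nasal", "temporal"),
      depth = ifelse(stats::runif(length(sp)) < config$small_anterior_prob,
                     "anterior", "posterior"),
      stringsAsFactors = FALSE)
  } else {
    sectors <- data.frame(patient_id = character(0),
                          age_quartile = integer(0),
                          vertical = character(0), horizontal = character(0),
                          depth = character(0))
  }

  structure(list(patients = patients, eyes = eyes, tumors = tumors,
                 sectors = sectors, window = window, config = config,
                 seed = seed, detail = detail),
            class = "rb_cohort")
}

# Recompute derived metrics from the canonical perimeter (used by the
# generator and by cohort readers).
compute_tumor_metrics_from <- function(rec, window = cap_window()) {
  tmp <- list(perimeter = rec$perimeter_canonical)
  tmp <- compute_tumor_metrics(tmp, window)
  rec$centroid <- tmp$centroid
  rec$area_fraction <- tmp$area_fraction
  rec
}

#' @export
print.rb_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort (seed %s): %d patients, %d eyes, %d mapped tumors, %d small-tumor records\n",
    format(x$seed), nrow(x$patients), nrow(x$eyes), length(x$tumors),
    nrow(x$sectors)))
  invisible(x)
}

#' Tumor metadata table of a cohort
#'
#' One row per mapped tumor with identifiers, marks and derived metrics
#' (centroid in canonical right-eye orientation).
#'
#' @param cohort an \code{rb_cohort}.
#' @return data.frame.
#' @export
tumor_table <- function(cohort) {
  do.call(rbind, lapply(cohort$tumors, function(tr)
    data.frame(patient_id = tr$patient_id, eye_id = tr$eye_id,
               tumor_id = tr$tumor_id, side = tr$side,
               mutation = tr$mutation, age_months = tr$age_months,
               icrb_group = tr$icrb_group, age_quartile = tr$age_quartile,
               area_quartile = if (!is.null(tr$area_quartile)) tr$area_quartile else NA,
               centroid_eccentricity = tr$centroid$eccentricity,
               centroid_polar_angle = tr$centroid$polar_angle,
               area_fraction = tr$area_fraction,
               stringsAsFactors = FALSE)))
}

#' Marked centroid point pattern of a cohort
#'
#' @param cohort an \code{rb_cohort}.
#' @return a \code{point_pattern} of projected centroids with marks
#'   \code{mutation}, \code{age_quartile}, \code{area_quartile},
#'   \code{eye_id}.
#' @export
centroid_pattern <- function(cohort) {
  tt <- tumor_table(cohort)
  q <- project(retinal_point(tt$centroid_eccentricity, tt$centroid_polar_angle))
  point_pattern(q$x, q$y,
                marks = tt[, c("mutation", "age_quartile", "area_quartile",
                               "eye_id")],
                window = cohort$window)
}

#' Table-1-style cohort summary
#'
#' Counts and percentages by laterality, mutation, age quartile, eye side and
#' ICRB group, in a layout that feeds the contingency-table tests directly.
#'
#' @param cohort an \code{rb_cohort}.
#' @return list of data.frames (\code{laterality}, \code{mutation},
#'   \code{age_quartile}, \code{side}, \code{icrb_group}), each with
#'   \code{count} and \code{percent}.
#' @export
summarize_cohort <- function(cohort) {
  pct_tab <- function(v) {
    tb <- table(v)
    data.frame(level = names(tb), count = as.integer(tb),
               percent = 100 * as.integer(tb) / sum(tb),
               stringsAsFactors = FALSE)
  }
  list(laterality = pct_tab(cohort$patients$laterality),
       mutation = pct_tab(cohort$patients$mutation),
       age_quartile = pct_tab(cohort$patients$age_quartile),
       side = pct_tab(cohort$eyes$side),
       icrb_group = pct_tab(cohort$eyes$icrb_group),
       n_patients = nrow(cohort$patients), n_eyes = nrow(cohort$eyes),
       n_tumors = length(cohort$tumors))
}
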