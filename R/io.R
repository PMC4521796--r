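#' Write a cohort to perimeter CSV and metadata JSON
#'
#' The perimeter CSV holds one row per measured vertex in the eye's own
#' orientation (\code{patient_id, eye_id, tumor_id, vertex_index,
#' eccentricity_deg, polar_angle_deg}); the metadata JSON holds the patient
#' table, eye table, per-tumor marks, sector records, window and seed.
#' Angles are serialized in degrees with 6 decimals.
#'
#' @param cohort an \code{rb_cohort} (detail \code{"full"}).
#' @param perimeter_csv,metadata_json output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, perimeter_csv, metadata_json) {
  if (!length(cohort$tumors) || is.null(cohort$tumors[[1]]$perimeter))
    stop("cohort has no perimeters to write (generated with detail='centroids'?)")
  rows <- do.call(rbind, lapply(cohort$tumors, function(tr)
    data.frame(patient_id = tr$patient_id, eye_id = tr$eye_id,
               tumor_id = tr$tumor_id,
               vertex_index = seq_len(nrow(tr$perimeter)),
               eccentricity_deg = round(tr$perimeter$eccentricity, 6),
               polar_angle_deg = round(tr$perimeter$polar_angle, 6),
               stringsAsFactors = FALSE)))
  utils::write.csv(rows, perimeter_csv, row.names = FALSE)
  meta <- list(
    patients = cohort$patients,
    eyes = cohort$eyes,
    tumors = do.call(rbind, lapply(cohort$tumors, function(tr)
      data.frame(tumor_id = tr$tumor_id, patient_id = tr$patient_id,
                 eye_id = tr$eye_id, side = tr$side, mutation = tr$mutation,
                 age_months = tr$age_months, icrb_group = tr$icrb_group,
                 stringsAsFactors = FALSE))),
    sectors = cohort$sectors,
    window_radius = cohort$window$radius,
    seed = cohort$seed)
  jsonlite::write_json(meta, metadata_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(perimeter_csv, metadata_json))
}

#' Read a cohort from perimeter CSV and metadata JSON
#'
#' Vertices are grouped by tumor in index order; left-eye perimeters are
#' canonicalized on load (the measured orientation is retained in the
#' record), derived centroid/area metrics and per-cohort quartile marks are
#' computed, and malformed records are collected in a validation report
#' rather than dropped silently.
#'
#' @param perimeter_csv,metadata_json input paths.
#' @return an \code{rb_cohort}; attribute \code{validation} lists flagged
#'   records and the reason.
#' @export
read_cohort <- function(perimeter_csv, metadata_json) {
  if (!file.exists(perimeter_csv)) stop("missing file: ", perimeter_csv)
  if (!file.exists(metadata_json)) stop("missing file: ", metadata_json)
  rows <- utils::read.csv(perimeter_csv, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye_id", "tumor_id", "vertex_index",
            "eccentricity_deg", "polar_angle_deg")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  meta <- jsonlite::read_json(metadata_json, simplifyVector = TRUE)
  window <- cap_window(if (!is.null(meta$window_radius)) meta$window_radius else 60)
  tm <- as.data.frame(meta$tumors)
  if (!all(unique(rows$tumor_id) %in% tm$tumor_id))
    stop("referential-integrity error: perimeter rows for tumors absent from metadata")
  if (!all(tm$tumor_id %in% unique(rows$tumor_id)))
    stop("referential-integrity error: metadata references absent tumor_id")
  flagged <- list()
  tumors <- list()
  for (id in tm$tumor_id) {
    vr <- rows[rows$tumor_id == id, ]
    vr <- vr[order(vr$vertex_index), ]
    info <- tm[tm$tumor_id == id, ]
    if (nrow(vr) < 3) {
      flagged[[id]] <- "fewer than 3 vertices"
      next
    }
    if (any(vr$eccentricity_deg < 0 | vr$eccentricity_deg > window$radius)) {
      flagged[[id]] <- "vertex out of mapped window"
      next
    }
    per <- retinal_point(vr$eccentricity_deg, vr$polar_angle_deg)
    rec <- list(patient_id = info$patient_id, eye_id = info$eye_id,
                tumor_id = id, side = info$side, mutation = info$mutation,
                age_months = info$age_months, icrb_group = info$icrb_group,
                perimeter = per,
                perimeter_canonical = canonicalize(per, info$side))
    rec <- compute_tumor_metrics_from(rec, window)
    tumors[[length(tumors) + 1L]] <- rec
  }
  patients <- as.data.frame(meta$patients)
  if (is.null(patients$age_quartile) && !is.null(patients$age_months))
    patients$age_quartile <- quartile_split(patients$age_months)$quartile
  qrt_of <- stats::setNames(patients$age_quartile, patients$patient_id)
  if (length(tumors)) {
    afs <- vapply(tumors, `[[`, 0, "area_fraction")
    aq <- if (length(afs) >= 4) quartile_split(afs)$quartile
          else rep(1L, length(afs))
    for (i in seq_along(tumors)) {
      tumors[[i]]$area_quartile <- aq[i]
      tumors[[i]]$age_quartile <- unname(qrt_of[tumors[[i]]$patient_id])
    }
  }
  out <- structure(list(patients = patients, eyes = as.data.frame(meta$eyes),
                        tumors = tumors, sectors = as.data.frame(meta$sectors),
                        window = window, config = NULL, seed = meta$seed,
                        detail = "full"),
                   class = "rb_cohort")
  attr(out, "validation") <- flagged
  out
}

#' Render a polar map of the retina
#'
#' Draws the azimuthal equidistant graticule (eccentricity rings and
#' meridians, superior up, nasal right for the canonical right eye, optic
#' disc marker at its polar angle) and overlays any of: a burden/density
#' matrix, tumor boundaries, centroids.
#'
#' @param burden optional matrix (with \code{grid} attribute) to show as an
#'   image layer.
#' @param boundaries optional list of \code{retinal_point} boundaries.
#' @param centroids optional \code{retinal_point} data.frame.
#' @param window a \code{cap_window}.
#' @param file optional output path; rendered with \code{grDevices::pdf}
#'   when it ends in .pdf, \code{png} otherwise. NULL draws on the current
#'   device.
#' @param main plot title.
#' @param palette color function for the image layer.
#' @param mirror draw in original left-eye orientation (mirrors the map).
#' @return invisibly, \code{file} (or NULL).
#' @export
render_polar_map <- function(burden = NULL, boundaries = NULL,
                             centroids = NULL, window = cap_window(),
                             file = NULL, main = "",
                             palette = grDevices::hcl.colors,
                             mirror = FALSE) {
  if (is.null(burden) && is.null(boundaries) && is.null(centroids))
    warning("no layers supplied; rendering a blank graticule")
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 6, height = 6)
    else grDevices::png(file, width = 720, height = 720)
    on.exit(grDevices::dev.off())
  }
  R <- window$radius
  sgn <- if (mirror) -1 else 1
  op <- graphics::par(mar = c(1, 1, 2, 1), pty = "s")
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(-R, R) * 1.08, ylim = c(-R, R) * 1.08,
                 axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
  if (!is.null(burden)) {
    g <- attr(burden, "grid")
    img <- t(burden)             # image() wants x as rows
    if (mirror) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    graphics::image(g$x, g$y, img, add = TRUE, col = palette(64),
                    useRaster = TRUE)
  }
  th <- seq(0, 2 * pi, length.out = 361)
  for (ring in seq(10, R, by = 10))
    graphics::lines(ring * sin(th), ring * cos(th), col = "grey60",
                    lty = if (ring == R) 1 else 3)
  for (mer in seq(0, 330, by = 30)) {
    graphics::lines(c(0, R * sin(.deg2rad(mer))) * sgn,
                    c(0, R * cos(.deg2rad(mer))), col = "grey85", lty = 3)
  }
  od <- .deg2rad(window$optic_disc_polar_angle)
  graphics::points(15 * sin(od) * sgn, 15 * cos(od), pch = 19, cex = 1.2,
                   col = "grey30")
  if (!is.null(boundaries))
    for (b in boundaries) {
      q <- project(b)
      graphics::polygon(q$x * sgn, q$y, border = "firebrick", lwd = 1)
    }
  if (!is.null(centroids)) {
    q <- project(centroids)
    graphics::points(q$x * sgn, q$y, pch = 21, bg = "steelblue")
  }
  graphics::text(0, R * 1.05, "S", cex = .8)
  graphics::text(R * 1.05 * sgn, 0, "N", cex = .8)
  invisible(file)
}

#' Export a burden map as plain-text matrix
#'
#' @param burden matrix with \code{grid} attribute.
#' @param file output path (tab-separated; NA outside the window).
#' @export
write_burden_matrix <- function(burden, file) {
  m <- burden
  g <- attr(burden, "grid")
  if (!is.null(g)) m[!g$inside] <- NA
  utils::write.table(m, file, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}
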