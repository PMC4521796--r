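#' Pipeline run configuration
#'
#' @param window_radius mapped window radius, degrees.
#' @param pitch raster pitch for burden maps, degrees.
#' @param degree polynomial degree of the log-intensity fits.
#' @param n_envelope CSR envelope simulations.
#' @param B permutation draws.
#' @param seed integer seed, recorded in every output.
#' @param out_dir output directory (created if missing); NULL keeps results
#'   in memory only.
#' @param figures write figures (PDF) alongside the JSON results.
#' @param cohort optional existing \code{rb_cohort}; by default a synthetic
#'   cohort is generated from \code{cohort_config()} at \code{seed}.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(window_radius = 60, pitch = 0.5, degree = 2,
                       n_envelope = 99, B = 999, seed = 1, out_dir = NULL,
                       figures = FALSE, cohort = NULL) {
  stopifnot(window_radius > 0, pitch > 0, degree >= 0, n_envelope >= 1)
  structure(list(window_radius = window_radius, pitch = pitch,
                 degree = degree, n_envelope = n_envelope, B = B,
                 seed = seed, out_dir = out_dir, figures = figures,
                 cohort = cohort), class = "run_config")
}

#' Run the full tumor-mapping analysis pipeline
#'
#' Executes, in order: cohort generation (or intake), per-tumor metrics,
#' cumulative burden maps (eye counts and per-age-quartile overlap
#' fractions), quartile splits, per-age-quartile inhomogeneous Poisson
#' intensity fits, Ripley's K with a CSR envelope, nearest-neighbour
#' comparison of great-circle vs projected Euclidean metrics, the
#' within-eye permutation test, relative density maps, and the cohort
#' summary tables with exact/rank tests. Any stage failure aborts with the
#' stage name; completed stage outputs are preserved in the error condition.
#'
#' @param config a \code{run_config}.
#' @return list of class \code{pipeline_result} with one element per stage
#'   plus \code{seed} and \code{config}; written to
#'   \code{<out_dir>/results.json} when an output directory is set.
#' @export
pipeline_run <- function(config = run_config()) {
  if (config$B < 1) stop("stage permutation: B must be >= 1")
  res <- list(seed = config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  window <- cap_window(config$window_radius)

  cohort <- stage("cohort", {
    if (!is.null(config$cohort)) config$cohort
    else generate_cohort(cohort_config(window = window), seed = config$seed)
  })
  res$summary <- stage("summary", summarize_cohort(cohort))
  tt <- stage("metrics", tumor_table(cohort))
  res$tumors <- tt

  grid <- raster_grid(config$pitch, window)
  res$burden <- stage("burden",
    cumulative_burden(cohort$tumors, grid, "eye_count"))
  res$burden_max_eyes <- max(res$burden)
  res$quartile_burden <- stage("quartile_burden",
    cumulative_burden(cohort$tumors, grid, "quartile_fraction"))

  pat <- stage("pattern", centroid_pattern(cohort))
  res$intensity <- stage("fit_ppm", {
    fit <- fit_intensity(pat, degree = config$degree,
                         mark_formula = "age_quartile")
    list(degree = fit$degree, loglik = fit$loglik, aic = fit$aic,
         coefficients = fit$coefficients)
  })
  res$k <- stage("kest", {
    k <- k_function(pat)
    env <- csr_envelope(pat, n_sim = config$n_envelope,
                        seed = config$seed + 1000L, r_grid = k$r)
    frac_above <- mean(k$k > env$hi)
    list(r = k$r, k = k$k, theo = k$theo, env_lo = env$lo, env_hi = env$hi,
         fraction_above_envelope = frac_above)
  })
  res$nn <- stage("nn", {
    gc <- nn_distances(pat, "great_circle")
    eu <- nn_distances(pat, "projected_euclidean")
    list(mean_great_circle = mean(gc), mean_euclidean = mean(eu),
         wilcoxon = wilcoxon_rank_sum(eu, gc))
  })
  res$permutation <- stage("permtest", {
    ctr <- retinal_point(tt$centroid_eccentricity, tt$centroid_polar_angle)
    pr <- within_eye_permutation_test(ctr, tt$eye_id, B = config$B,
                                      seed = config$seed + 2000L)
    list(observed = pr$observed, p_value = pr$p_value, B = pr$B)
  })
  res$relative_density <- stage("density", {
    rd <- lapply(1:4, function(q) {
      sel <- pat$marks$age_quartile == q
      if (sum(sel) < 2) return(NULL)
      relative_density_map(point_pattern(pat$x[sel], pat$y[sel],
                                         window = window),
                           raster_grid(2, window), bandwidth = 10)
    })
    names(rd) <- paste0("Q", 1:4)
    rd
  })
  res$tables <- stage("tables", {
    p <- cohort$patients
    mut_lat <- table(p$mutation, p$laterality)
    list(
      mutation_by_laterality = as.matrix(mut_lat),
      fisher_mut_lat = if (all(dim(mut_lat) == 2))
        fisher_exact(as.matrix(mut_lat)) else NULL,
      age_by_mutation = wilcoxon_rank_sum(
        p$age_months[p$mutation == "germline"],
        p$age_months[p$mutation == "somatic"]),
      sector = if (nrow(cohort$sectors))
        sector_tally(cohort$sectors$vertical, cohort$sectors$age_quartile)
      else NULL)
  })
  res$config <- config[setdiff(names(config), "cohort")]
  class(res) <- "pipeline_result"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    keep <- res[setdiff(names(res), c("burden", "quartile_burden",
                                      "relative_density"))]
    keep$config$out_dir <- NULL      # keep results path-independent
    if (!is.null(keep$tables$sector))
      keep$tables$sector$table <- as.matrix(keep$tables$sector$table)
    jsonlite::write_json(keep, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = 10, force = TRUE,
                         na = "null")
    write_burden_matrix(res$burden,
                        file.path(config$out_dir, "burden_eye_count.tsv"))
    if (config$figures) {
      render_polar_map(burden = res$burden, window = window,
                       file = file.path(config$out_dir, "burden.pdf"),
                       main = "cumulative tumor burden (eyes)")
      ctr <- retinal_point(tt$centroid_eccentricity, tt$centroid_polar_angle)
      render_polar_map(centroids = ctr, window = window,
                       file = file.path(config$out_dir, "centroids.pdf"),
                       main = "tumor centroids")
    }
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result (seed %s): %d tumors; permutation p = %.4g\n",
              format(x$seed), nrow(x$tumors), x$permutation$p_value))
  invisible(x)
}
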