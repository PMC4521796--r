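#' Fisher's exact test on a contingency table
#'
#' Two-sided exact test for a 2 x K table of counts with fixed margins; p by
#' the point-probability rule (sum of table probabilities no larger than the
#' observed one). For 2 x 2 tables the reported odds ratio is the conditional
#' maximum-likelihood estimate under the noncentral hypergeometric model.
#'
#' @param table matrix of nonnegative integer counts, at least 2 x 2.
#' @return list with \code{p_value}, \code{odds_ratio} (NA beyond 2 x 2 or
#'   when undefined by a zero margin) and \code{or_defined}.
#' @examples
#' fisher_exact(matrix(c(28, 11, 24, 43), 2, byrow = TRUE))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("table must be at least 2 x 2")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_, or_defined = FALSE))
  ft <- stats::fisher.test(table)
  is2x2 <- all(dim(table) == 2)
  list(p_value = ft$p.value,
       odds_ratio = if (is2x2) unname(ft$estimate) else NA_real_,
       or_defined = is2x2)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum comparison of two samples; W is the Mann-Whitney U
#' statistic for the first sample. Exact p for small samples without ties,
#' normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples (both nonempty).
#' @return list with \code{W} and \code{p_value}.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(W = unname(wt$statistic), p_value = wt$p.value)
}

#' Quartile split of a numeric variable
#'
#' Cut points at the 25/50/75 empirical percentiles (linear interpolation
#' between order statistics); values equal to a cut point go to the lower
#' quartile.
#'
#' @param values numeric vector (>= 4 values).
#' @param type percentile definition passed to \code{\link[stats]{quantile}}
#'   (default 7, linear interpolation).
#' @return list with \code{cuts} (length 3) and \code{quartile}
#'   (integer 1..4 per value).
#' @examples
#' quartile_split(1:8)$cuts  # 2.75 4.5 6.25
#' @export
quartile_split <- function(values, type = 7) {
  if (length(values) < 4) stop("need at least 4 values")
  cuts <- unname(stats::quantile(values, c(.25, .5, .75), type = type))
  if (any(diff(cuts) <= 0))
    warning("degenerate quartile cuts (ties)")
  q <- 1L + (values > cuts[1]) + (values > cuts[2]) + (values > cuts[3])
  list(cuts = cuts, quartile = as.integer(q))
}

#' Superior/inferior sector tally with exact test
#'
#' Tabulates fundoscopy-only small tumors by superior vs inferior hemisphere
#' against age quartile and tests the proportions with Fisher's exact test.
#' Records on the equatorial meridian (neither superior nor inferior) are
#' excluded from the tally.
#'
#' @param vertical sector label per tumor: \code{"superior"},
#'   \code{"inferior"} or \code{"meridian"}.
#' @param age_quartile integer 1..4 per tumor.
#' @return list with the 2 x K \code{table} (K = quartiles present),
#'   \code{p_value}, and \code{n_excluded} meridian records.
#' @export
sector_tally <- function(vertical, age_quartile) {
  vertical <- as.character(vertical)
  bad <- setdiff(unique(vertical), c("superior", "inferior", "meridian"))
  if (length(bad)) stop("unknown sector label: ", paste(bad, collapse = ", "))
  if (any(!age_quartile %in% 1:4)) stop("age_quartile must be 1..4")
  keep <- vertical != "meridian"
  tab <- table(factor(vertical[keep], c("superior", "inferior")),
               factor(age_quartile[keep], 1:4))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  p <- if (ncol(tab) < 2 || any(rowSums(tab) == 0)) 1
       else stats::fisher.test(tab)$p.value
  list(table = tab, p_value = p, n_excluded = sum(!keep))
}

#' Circular mean of polar angles
#'
#' Direction of the mean unit vector of a set of angles (degrees) and its
#' resultant length in \code{[0, 1]}. An antipodally balanced set has an
#' undefined direction, flagged by \code{defined = FALSE}.
#'
#' @param angles polar angles in degrees.
#' @return list with \code{mean} (degrees in \code{[0, 360)}, NA when
#'   undefined), \code{resultant} and \code{defined}.
#' @export
circular_mean <- function(angles) {
  if (!length(angles)) stop("need at least one angle")
  th <- .deg2rad(angles)
  s <- mean(sin(th)); c <- mean(cos(th))
  r <- sqrt(s^2 + c^2)
  if (r < 1e-12)
    return(list(mean = NA_real_, resultant = 0, defined = FALSE))
  m <- .rad2deg(atan2(s, c)) %% 360
  if (m >= 360 - 1e-9) m <- 0
  list(mean = m, resultant = r, defined = TRUE)
}
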