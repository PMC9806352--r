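# Linear interpolation of a lane profile at arbitrary migration positions.
profile_at <- function(profile, x) {
  stats::approx(profile$position, profile$intensity, xout = x,
                method = "linear", rule = 1)$y
}

check_bands_in_range <- function(profile, bands) {
  lo <- profile$position[1]
  hi <- profile$position[nrow(profile)]
  bad <- bands$start < lo | bands$end > hi
  if (any(bad)) {
    stop_venomcomp(
      sprintf("band(s) outside profile range [%g, %g]: %s", lo, hi,
              paste(bands$band_id[bad], collapse = ", ")),
      "venomcomp_bounds_error"
    )
  }
}

#' Valley-to-valley baseline subtraction
#'
#' For each band, the straight line through the profile values at the band's
#' start and end (the flanking valleys) is subtracted inside the band and
#' the result is clipped at zero; the profile outside bands is unchanged.
#' This is the simplest defensible background model for gel lanes, where the
#' staining background varies slowly along the migration axis.
#'
#' @param profile a [lane_profile()].
#' @param bands a [band_definitions()] table lying within the profile range.
#' @return a corrected \code{lane_profile}.
#' @export
subtract_baseline <- function(profile, bands) {
  check_bands_in_range(profile, bands)
  x <- profile$position
  y <- profile$intensity
  for (i in seq_len(nrow(bands))) {
    s <- bands$start[i]; e <- bands$end[i]
    y0 <- profile_at(profile, s)
    y1 <- profile_at(profile, e)
    inside <- x >= s & x < e
    base <- y0 + (y1 - y0) * (x[inside] - s) / (e - s)
    y[inside] <- pmax(0, y[inside] - base)
  }
  lane_profile(x, y)
}

#' Integrate band areas and densitometric proportions
#'
#' Each band's area is the exact integral of the piecewise-linear profile
#' over \code{[start, end)} (trapezoidal rule with interpolated boundary
#' points, so the result is invariant to resampling of a piecewise-linear
#' signal). Proportions are normalised over the analysed bands only: the
#' weighting scheme assumes the quantified bands are the excised ones, and
#' the composition sums to 100\% only under this convention.
#'
#' @param profile a [lane_profile()], normally baseline-corrected first.
#' @param bands a [band_definitions()] table.
#' @return A \code{band_proportions} data frame with columns \code{band_id},
#'   \code{area}, \code{proportion}; proportions sum to 1.
#' @export
integrate_bands <- function(profile, bands) {
  check_bands_in_range(profile, bands)
  areas <- vapply(seq_len(nrow(bands)), function(i) {
    s <- bands$start[i]; e <- bands$end[i]
    inner <- profile$position[profile$position > s & profile$position < e]
    xs <- c(s, inner, e)
    ys <- profile_at(profile, xs)
    sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
  }, numeric(1))
  proportions_from_areas(setNames(areas, bands$band_id))
}

#' Band proportions from a precomputed area table
#'
#' Entry point for lanes quantified in external gel software: converts
#' per-band areas into densitometric proportions by proportional
#' normalisation.
#'
#' @param areas named numeric vector (or data frame with \code{band_id},
#'   \code{area}) of non-negative band areas, at least one positive.
#' @return A \code{band_proportions} data frame; proportions sum to 1.
#' @export
proportions_from_areas <- function(areas) {
  if (is.data.frame(areas)) {
    areas <- setNames(as.numeric(areas$area), as.character(areas$band_id))
  }
  if (any(areas < 0)) {
    stop_venomcomp("band areas must be >= 0", "venomcomp_validation_error")
  }
  total <- sum(areas)
  if (total <= 0) {
    stop_venomcomp("degenerate lane: all band areas are zero",
                   "venomcomp_degenerate_error")
  }
  df <- data.frame(band_id = names(areas), area = as.numeric(areas),
                   proportion = as.numeric(areas) / total,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("band_proportions", "data.frame"))
}
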