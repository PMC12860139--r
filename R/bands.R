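#' Monthly-migraine-day (MMD) severity bands
#'
#' The model's state space: six disjoint bands of integer monthly migraine
#' days. The lower three bands are episodic migraine (EM, < 15 MMDs), the
#' upper three chronic migraine (CM, >= 15 MMDs). Display labels follow the
#' transition-probability table ("20-24", "24+"); the underlying integer
#' intervals are disjoint (20-23, >= 24).
#'
#' @return A data.frame with one row per band: `label`, `lower`, `upper`
#'   (`Inf` for the open top band) and `is_chronic`.
#' @export
#' @examples
#' mmd_bands()
mmd_bands <- function() {
  data.frame(
    label      = c("0-3", "4-9", "10-14", "15-19", "20-24", "24+"),
    lower      = c(0, 4, 10, 15, 20, 24),
    upper      = c(3, 9, 14, 19, 23, Inf),
    is_chronic = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' @rdname mmd_bands
#' @export
band_labels <- function() mmd_bands()$label

#' Representative MMD value for each band
#'
#' Band midpoints used to summarise a cohort trace as an expected MMD count.
#' The open "24+" band has no midpoint and is represented by 26 by default.
#'
#' @param top_band_value Representative value for the "24+" band.
#' @return Named numeric vector of length six.
#' @export
band_midpoints <- function(top_band_value = 26) {
  stats::setNames(c(1.5, 6.5, 12, 17, 21.5, top_band_value), band_labels())
}

#' Map an MMD count to its severity band
#'
#' Fractional MMD values are rounded half-up to the nearest integer day
#' before banding, so the bands are total and single-valued over all
#' non-negative inputs.
#'
#' @param mmd Numeric vector of monthly migraine days, all >= 0.
#' @return Character vector of band labels (factor-free).
#' @export
#' @examples
#' band_of_mmd(c(0, 10, 20.4))
band_of_mmd <- function(mmd) {
  if (!is.numeric(mmd) || anyNA(mmd)) {
    stop("`mmd` must be numeric with no missing values", call. = FALSE)
  }
  if (any(mmd < 0)) {
    stop("monthly migraine days cannot be negative", call. = FALSE)
  }
  days <- floor(mmd + 0.5) # round half up; bands are defined on integer days
  b <- mmd_bands()
  idx <- findInterval(days, b$lower)
  b$label[idx]
}

#' @rdname band_of_mmd
#' @param label Character vector of band labels.
#' @return `band_index()` returns the integer position (1-6) of each label.
#' @export
band_index <- function(label) {
  idx <- match(label, band_labels())
  if (anyNA(idx)) {
    stop("unknown band label(s): ",
         paste(unique(label[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}
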