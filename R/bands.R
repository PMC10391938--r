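#' Narrowband filter bank definitions
#'
#' The detector scans the EEG with a set of overlapping narrow bands so that
#' any oscillation between 2 and 14 Hz falls well inside at least one
#' passband. The default set is 2-6, 4-8, 6-10, 8-12 and 10-14 Hz.
#'
#' @param low Low passband edge in Hz.
#' @param high High passband edge in Hz.
#' @param label Optional label; defaults to "low-high".
#' @return An object of class `band_definition` with elements `label`, `low`,
#'   `high`.
#' @examples
#' band_definition(6, 10)
#' @export
band_definition <- function(low, high, label = NULL) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (!(low > 0 && high > low))
    stop("band edges must satisfy 0 < low < high")
  if (is.null(label)) label <- sprintf("%g-%g", low, high)
  structure(list(label = label, low = low, high = high),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("band %s: %g-%g Hz (cycle period %.4g-%.4g s)\n",
              x$label, x$low, x$high, 1 / x$high, 1 / x$low))
  invisible(x)
}

#' Default overlapping band set for burst detection
#'
#' @return A named list of [band_definition()] objects covering 2-14 Hz in
#'   overlapping 4 Hz bands.
#' @export
default_bands <- function() {
  edges <- list(c(2, 6), c(4, 8), c(6, 10), c(8, 12), c(10, 14))
  bands <- lapply(edges, function(e) band_definition(e[1], e[2]))
  names(bands) <- vapply(bands, `[[`, "", "label")
  bands
}

#' Admissible cycle-period range of a band
#'
#' Criterion B of the per-cycle tests requires a cycle's mean period (distance
#' between neighbouring negative peaks) to lie within the period range of the
#' filter band: a 6-10 Hz band admits periods between 0.1 and 0.1667 s.
#'
#' @param band A [band_definition()].
#' @return Numeric vector `c(min_period_s, max_period_s)` = `c(1/high, 1/low)`.
#' @export
band_period_range <- function(band) {
  stopifnot(inherits(band, "band_definition"))
  c(1 / band$high, 1 / band$low)
}
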