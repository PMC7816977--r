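#' Construct a powder X-ray diffraction pattern
#'
#' @param two_theta strictly increasing diffraction angles, degrees,
#'   within (0, 90).
#' @param intensity counts, >= 0, same length.
#' @param label text identifier.
#' @return object of class `diffraction_pattern`.
#' @export
diffraction_pattern <- function(two_theta, intensity, label = "pattern") {
  two_theta <- as.numeric(two_theta); intensity <- as.numeric(intensity)
  if (length(two_theta) != length(intensity))
    stop("`two_theta` and `intensity` must have equal length", call. = FALSE)
  if (any(diff(two_theta) <= 0))
    stop("`two_theta` must be strictly increasing", call. = FALSE)
  if (any(two_theta <= 0 | two_theta >= 90))
    stop("`two_theta` must lie within (0, 90) degrees", call. = FALSE)
  if (any(intensity < 0))
    stop("`intensity` must be >= 0", call. = FALSE)
  structure(list(two_theta = two_theta, intensity = intensity,
                 label = as.character(label)[1L]),
            class = "diffraction_pattern")
}

#' Read a two-column diffraction pattern from CSV
#'
#' Expected columns: `two_theta,intensity`.
#'
#' @param path CSV path.
#' @param label identifier; default the file name.
#' @return a `diffraction_pattern`.
#' @export
read_pattern <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  if (!all(c("two_theta", "intensity") %in% names(d)))
    stop("pattern CSV must have columns 'two_theta' and 'intensity'",
         call. = FALSE)
  diffraction_pattern(d$two_theta, d$intensity, label)
}

#' Baseline-corrected peak height at a diffraction angle
#'
#' The maximum intensity within the closed window
#' `[angle - window/2, angle + window/2]`, after subtracting the straight
#' line through the window's endpoint samples (a local linear baseline),
#' floored at 0. Raw height ratios without baseline handling are not
#' comparable across instruments; `baseline = FALSE` disables the
#' correction for patterns already background-subtracted.
#'
#' @param pattern a `diffraction_pattern`.
#' @param angle nominal peak position, degrees 2-theta.
#' @param window full window width, degrees (default 1, i.e. +/- 0.5).
#' @param baseline subtract the endpoint-line baseline (default `TRUE`).
#' @return peak height in counts (>= 0).
#' @export
peak_height <- function(pattern, angle, window = 1, baseline = TRUE) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  lo <- angle - window / 2; hi <- angle + window / 2
  rng <- range(pattern$two_theta)
  if (lo < rng[1L] || hi > rng[2L])
    stop(sprintf("window [%g, %g] extends outside the data range [%g, %g]",
                 lo, hi, rng[1L], rng[2L]), call. = FALSE)
  sel <- pattern$two_theta >= lo & pattern$two_theta <= hi
  x <- pattern$two_theta[sel]; y <- pattern$intensity[sel]
  if (length(x) < 3L)
    stop("fewer than 3 pattern points inside the window", call. = FALSE)
  if (baseline) {
    n <- length(x)
    slope <- (y[n] - y[1L]) / (x[n] - x[1L])
    y <- y - (y[1L] + slope * (x - x[1L]))
  }
  max(max(y), 0)
}

#' Degree of relative crystallinity (DRC)
#'
#' Ratio of the sample's to the reference's peak height at a
#' characteristic angle, DRC = I_sample / I_reference. Values near 0
#' indicate amorphization of the sample relative to the (crystalline)
#' reference; for a drug amorphized inside a solid-dispersion matrix the
#' principal reflection essentially vanishes. The raw ratio is returned;
#' report tables conventionally round it to 2 decimals.
#'
#' @param sample,reference `diffraction_pattern` objects covering the
#'   window.
#' @param angle characteristic peak position, degrees 2-theta.
#' @inheritParams peak_height
#' @return dimensionless ratio.
#' @export
relative_crystallinity <- function(sample, reference, angle, window = 1,
                                   baseline = TRUE) {
  i_ref <- peak_height(reference, angle, window, baseline)
  if (i_ref <= 0)
    stop(sprintf("reference peak absent at angle %g", angle), call. = FALSE)
  peak_height(sample, angle, window, baseline) / i_ref
}
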