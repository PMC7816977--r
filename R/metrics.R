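#' Similarity factor f2 between two dissolution profiles
#'
#' The model-independent similarity factor
#' \deqn{f_2 = 50 \log_{10}\left\{100 \left[1 + \frac{1}{n}\sum_{t=1}^{n}
#'   (R_t - T_t)^2\right]^{-1/2}\right\}}
#' where \eqn{R_t} and \eqn{T_t} are the reference and test percent
#' dissolved at the n shared sampling times. Identical profiles score
#' exactly 100; a constant 10-point gap at every time scores about 50, the
#' conventional similar/different boundary (f2 < 50 indicates a
#' significantly different profile).
#'
#' The t = 0 point carries no information (both profiles are 0 by
#' definition) and is excluded by default. With `truncate_85 = TRUE` the
#' FDA rule of keeping at most one point after both profiles pass 85%
#' dissolved is applied before scoring; the default uses all shared
#' post-zero points (the DD-Solver default).
#'
#' @param reference,test `dissolution_profile` objects on an identical time
#'   grid (see [align_profiles()]).
#' @param exclude_zero drop the t = 0 point (default `TRUE`).
#' @param truncate_85 apply the at-most-one-point-above-85% rule (default
#'   `FALSE`).
#' @return f2 score (dimensionless, upper bound 100).
#' @export
similarity_factor <- function(reference, test, exclude_zero = TRUE,
                              truncate_85 = FALSE) {
  stopifnot(inherits(reference, "dissolution_profile"),
            inherits(test, "dissolution_profile"))
  if (length(reference$times) != length(test$times) ||
      any(reference$times != test$times))
    stop("profiles are not on a common time grid; run align_profiles() first",
         call. = FALSE)
  keep <- rep(TRUE, length(reference$times))
  if (exclude_zero) keep <- keep & reference$times > 0
  R <- reference$dissolved[keep]
  Tt <- test$dissolved[keep]
  if (truncate_85) {
    over <- which(R >= 85 & Tt >= 85)
    if (length(over) > 1L) {
      last <- over[1L]
      R <- R[seq_len(last)]
      Tt <- Tt[seq_len(last)]
    }
  }
  n <- length(R)
  if (n < 3L)
    stop("need at least 3 usable shared time points for f2", call. = FALSE)
  msd <- sum((R - Tt)^2) / n
  50 * log10(100 / sqrt(1 + msd))
}

#' Dissolution efficiency (DE%)
#'
#' Percent ratio of the area under the cumulative dissolution curve up to
#' `t_end` to the area of the rectangle describing 100% dissolution over
#' the same window:
#' \deqn{DE\% = 100 \cdot \frac{\int_0^{t_{end}} y\,dt}{100 \cdot t_{end}}}
#' The integral uses the trapezoidal rule over the sampling points. A
#' profile lacking a t = 0 point is anchored at (0, 0) — the dose is
#' undissolved when the test starts. If `t_end` falls between sampling
#' points the curve is linearly interpolated there; extrapolation beyond
#' the data is refused.
#'
#' @param profile a `dissolution_profile`.
#' @param t_end end of the integration window, minutes.
#' @return DE in percent.
#' @export
dissolution_efficiency <- function(profile, t_end) {
  stopifnot(inherits(profile, "dissolution_profile"))
  if (length(t_end) != 1L || !is.finite(t_end) || t_end <= 0)
    stop("`t_end` must be a single positive time", call. = FALSE)
  tt <- profile$times
  yy <- profile$dissolved
  if (tt[1L] > 0) { tt <- c(0, tt); yy <- c(0, yy) }
  if (t_end > tt[length(tt)] + 1e-9)
    stop(sprintf("t_end = %g min is beyond the last sampling time (%g min); no extrapolation",
                 t_end, tt[length(tt)]), call. = FALSE)
  if (!any(abs(tt - t_end) < 1e-9)) {
    y_end <- stats::approx(tt, yy, xout = t_end)$y
    keep <- tt < t_end
    tt <- c(tt[keep], t_end)
    yy <- c(yy[keep], y_end)
  } else {
    keep <- tt <= t_end + 1e-9
    tt <- tt[keep]; yy <- yy[keep]
  }
  100 * pracma::trapz(tt, yy) / (100 * t_end)
}

#' Mean dissolution time (MDT)
#'
#' Increment-weighted mean of interval midpoints of the cumulative curve:
#' \deqn{MDT = \frac{\sum_j t^*_j \Delta M_j}{\sum_j \Delta M_j}}
#' with \eqn{t^*_j} the midpoint of sampling interval j and
#' \eqn{\Delta M_j} the additional percent dissolved in that interval.
#' Small MDT means fast release. For a fine-grid first-order release
#' \eqn{M(t) = 100(1 - e^{-kt})} MDT converges to \eqn{1/k}.
#'
#' Profiles lacking a t = 0 point are anchored at (0, 0) with a warning.
#' Negative increments (noisy cumulative data) are used as-is, matching the
#' literal formula, with a warning; use `monotonize = TRUE` to apply a
#' running-maximum pre-pass instead.
#'
#' @param profile a `dissolution_profile`.
#' @param monotonize apply a running-maximum monotonization first.
#' @return MDT in minutes.
#' @export
mean_dissolution_time <- function(profile, monotonize = FALSE) {
  stopifnot(inherits(profile, "dissolution_profile"))
  tt <- profile$times
  yy <- profile$dissolved
  if (monotonize) yy <- cummax(yy)
  if (tt[1L] > 0) {
    warning("profile lacks a t = 0 point; anchoring at (0, 0)", call. = FALSE)
    tt <- c(0, tt); yy <- c(0, yy)
  }
  dM <- diff(yy)
  if (all(dM == 0)) stop("no dissolution observed", call. = FALSE)
  if (any(dM < 0) && !monotonize)
    warning("cumulative curve decreases in places; negative increments used as-is",
            call. = FALSE)
  mid <- (tt[-1L] + tt[-length(tt)]) / 2
  sum(mid * dM) / sum(dM)
}

#' Monotonize a cumulative dissolution profile
#'
#' Running-maximum pre-pass for noisy cumulative curves that occasionally
#' decrease between sampling points.
#'
#' @param profile a `dissolution_profile`.
#' @return a `dissolution_profile` with non-decreasing values.
#' @export
monotonize_profile <- function(profile) {
  stopifnot(inherits(profile, "dissolution_profile"))
  suppress_over100(dissolution_profile(profile$times, cummax(profile$dissolved),
                                       profile$label, sd = profile$sd,
                                       n_replicates = profile$n_replicates))
}

#' Fold change between two positive quantities
#'
#' Reported half-even rounded to 2 decimals (the raw ratio is retained as
#' attribute `"raw"`). Used for headline statements such as the 10.83-fold
#' gain in 15-min dissolution efficiency of an optimized solid dispersion
#' over the plain drug.
#'
#' @param test_value,reference_value positive reals.
#' @return rounded ratio with attribute `raw`.
#' @export
fold_change <- function(test_value, reference_value) {
  if (!is.finite(reference_value) || reference_value <= 0)
    stop("reference value must be > 0", call. = FALSE)
  if (!is.finite(test_value) || test_value <= 0)
    stop("test value must be > 0", call. = FALSE)
  raw <- test_value / reference_value
  structure(round(raw, 2L), raw = raw)
}

#' Model-independent dissolution summary table
#'
#' Computes, per profile: dissolution efficiency at the requested times,
#' mean dissolution time, and the similarity factor versus a designated
#' reference profile — the layout of a formulation-screening response
#' table.
#'
#' @param profiles named list of `dissolution_profile` objects.
#' @param reference label of the reference profile for f2 (itself reported
#'   as `NA`); `NULL` skips f2.
#' @param de_times times (minutes) at which DE% is evaluated.
#' @return data.frame with one row per profile.
#' @export
dissolution_summary <- function(profiles, reference = NULL,
                                de_times = c(15, 60)) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  labs <- vapply(profiles, `[[`, "", "label")
  out <- data.frame(label = labs, stringsAsFactors = FALSE)
  for (tt in de_times)
    out[[sprintf("de%g", tt)]] <-
      vapply(profiles, dissolution_efficiency, 0, t_end = tt)
  out$mdt <- vapply(profiles, mean_dissolution_time, 0)
  if (!is.null(reference)) {
    if (!reference %in% labs)
      stop("reference label '", reference, "' not found among profiles",
           call. = FALSE)
    ref <- profiles[[match(reference, labs)]]
    out$f2_vs_reference <- vapply(profiles, function(p) {
      if (identical(p$label, reference)) return(NA_real_)
      al <- align_profiles(ref, p)
      similarity_factor(al$a, al$b)
    }, 0)
  }
  rownames(out) <- NULL
  out
}
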