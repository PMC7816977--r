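#' Generate a synthetic dissolution profile with known kinetics
#'
#' Seeded generator emulating cumulative percent-dissolved time courses of
#' the shapes seen in solid-dispersion screening: first-order
#' \eqn{M(t) = plateau(1 - e^{-kt})}, Weibull
#' \eqn{M(t) = plateau(1 - e^{-(t/\tau)^\beta})} (identical to first order
#' when \eqn{\beta = 1} and \eqn{\tau = 1/k}), zero-order
#' \eqn{M(t) = slope \cdot t} and Higuchi \eqn{M(t) = slope\sqrt t}.
#' The t = 0 point is exactly 0 before noise; i.i.d. Gaussian noise is then
#' added per point and floored at 0 (not capped at 100, matching observed
#' supra-100% assay values). Deterministic given `seed`.
#'
#' @param model `"first_order"`, `"weibull"`, `"zero_order"` or
#'   `"higuchi"`.
#' @param k first-order rate constant, 1/min.
#' @param tau,beta Weibull scale (min) and shape.
#' @param slope zero-order (%/min) or Higuchi (%/min^0.5) constant.
#' @param plateau asymptotic percent dissolved (default 100).
#' @param times sampling grid, minutes (default 0, 5, 10, 15, 30, 45, 60).
#' @param noise_sd Gaussian noise SD, percent (default 0).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param label profile label.
#' @return a [dissolution_profile].
#' @export
gen_dissolution_profile <- function(model = c("first_order", "weibull",
                                              "zero_order", "higuchi"),
                                    k = NULL, tau = NULL, beta = NULL,
                                    slope = NULL, plateau = 100,
                                    times = c(0, 5, 10, 15, 30, 45, 60),
                                    noise_sd = 0, seed = NULL,
                                    label = NULL) {
  model <- match.arg(model)
  stopifnot(noise_sd >= 0, plateau > 0, all(times >= 0))
  mean_curve <- switch(model,
    first_order = {
      stopifnot(!is.null(k), k > 0)
      plateau * (1 - exp(-k * times))
    },
    weibull = {
      stopifnot(!is.null(tau), tau > 0, !is.null(beta), beta > 0)
      plateau * (1 - exp(-(times / tau)^beta))
    },
    zero_order = {
      stopifnot(!is.null(slope), slope > 0)
      slope * times
    },
    higuchi = {
      stopifnot(!is.null(slope), slope > 0)
      slope * sqrt(times)
    })
  mean_curve[times == 0] <- 0
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    mean_curve <- pmax(0, mean_curve + stats::rnorm(length(times), 0, noise_sd))
  }
  if (is.null(label)) label <- paste0("synthetic_", model)
  suppress_over100(dissolution_profile(times, mean_curve, label))
}

#' Generate a factorial dataset with known coefficients
#'
#' Seeded generator mirroring the 18-run solid-dispersion design layout:
#' responses are computed from supplied coefficients on the coded model
#' matrix plus i.i.d. Gaussian noise, so coefficient recovery, ANOVA and
#' PRESS machinery can be tested against known truth. The default layout
#' reproduces the packaged design's replicate structure (six duplicated
#' settings), giving positive pure-error degrees of freedom.
#'
#' @param true_coefficients numeric vector conforming to the coded matrix
#'   of `model_order` (length 5 linear, 8 2FI, 9 quadratic).
#' @param model_order `"linear"`, `"2fi"` or `"quadratic"`.
#' @param noise_sd response-unit noise SD.
#' @param layout data.frame of `ratio_parts`/`polymer` rows; default the
#'   packaged design's 18 settings.
#' @param seed integer seed.
#' @param response name for the generated response column.
#' @return the design data.frame with the response appended; the
#'   generating coefficients are attached as attribute
#'   `"true_coefficients"`.
#' @export
gen_doe_dataset <- function(true_coefficients,
                            model_order = c("linear", "2fi", "quadratic"),
                            noise_sd = 0, layout = NULL, seed = NULL,
                            response = "y") {
  model_order <- match.arg(model_order)
  if (is.null(layout))
    layout <- diacerein_design()[, c("run", "ratio_parts", "polymer")]
  X <- encode_design(layout, model_order)
  if (length(true_coefficients) != ncol(X))
    stop(sprintf("expected %d coefficients for a %s model, got %d",
                 ncol(X), model_order, length(true_coefficients)),
         call. = FALSE)
  mu <- drop(X %*% true_coefficients)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    mu <- mu + stats::rnorm(length(mu), 0, noise_sd)
  }
  layout[[response]] <- mu
  attr(layout, "true_coefficients") <- stats::setNames(true_coefficients,
                                                       colnames(X))
  layout
}

#' Generate a synthetic powder XRD pattern
#'
#' Sum of Gaussian peaks on a constant baseline plus optional Gaussian
#' noise, emulating a diffractogram with a few marked reflections (e.g. a
#' crystalline drug's principal peaks at low angle). Deterministic given
#' `seed`.
#'
#' @param peaks data.frame with columns `angle` (degrees), `amplitude`
#'   (counts) and `width` (Gaussian SD, degrees); may have zero rows.
#' @param baseline constant background counts.
#' @param noise_sd Gaussian noise SD, counts.
#' @param two_theta sampling grid, degrees (default 2 to 40 by 0.02).
#' @param seed integer seed.
#' @param label pattern label.
#' @return a [diffraction_pattern].
#' @export
gen_xrd_pattern <- function(peaks, baseline = 100, noise_sd = 0,
                            two_theta = seq(2, 40, by = 0.02), seed = NULL,
                            label = "synthetic_pattern") {
  stopifnot(is.data.frame(peaks),
            all(c("angle", "amplitude", "width") %in% names(peaks)) ||
              nrow(peaks) == 0L)
  y <- rep(baseline, length(two_theta))
  if (nrow(peaks)) {
    if (any(peaks$angle < min(two_theta) | peaks$angle > max(two_theta)))
      stop("peak angle outside the sampling range", call. = FALSE)
    for (i in seq_len(nrow(peaks)))
      y <- y + peaks$amplitude[i] *
        exp(-(two_theta - peaks$angle[i])^2 / (2 * peaks$width[i]^2))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    y <- pmax(0, y + stats::rnorm(length(y), 0, noise_sd))
  }
  diffraction_pattern(two_theta, y, label)
}
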