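#' Construct a cumulative dissolution profile
#'
#' A dissolution profile is the pipeline's atomic input: a time course of
#' mean cumulative percent drug dissolved at strictly increasing sampling
#' times (minutes), optionally with per-time replicate standard deviations.
#'
#' Values above 100% are retained, not clipped: assay variability in
#' dispersed-powder dissolution tests routinely produces slightly
#' supra-nominal readings (e.g. 103.8% at 60 min for a fast-releasing solid
#' dispersion), and downstream statistics define their own handling. A
#' warning flags them.
#'
#' @param times numeric vector of sampling times in minutes, strictly
#'   increasing, all >= 0.
#' @param dissolved numeric vector of mean cumulative percent dissolved,
#'   same length as `times`, all >= 0.
#' @param label character scalar identifying the formulation/system.
#' @param sd optional numeric vector of replicate standard deviations (%).
#' @param n_replicates optional positive integer, number of replicates.
#' @return An object of class `dissolution_profile`: a list with elements
#'   `label`, `times`, `dissolved`, `sd`, `n_replicates`.
#' @examples
#' p <- dissolution_profile(c(0, 5, 15, 30, 60), c(0, 20, 45, 80, 98), "SD")
#' p
#' @export
dissolution_profile <- function(times, dissolved, label = "profile",
                                sd = NULL, n_replicates = NULL) {
  times <- as.numeric(times)
  dissolved <- as.numeric(dissolved)
  if (length(times) != length(dissolved))
    stop("`times` and `dissolved` must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("a dissolution profile needs at least 2 sampling points",
         call. = FALSE)
  if (anyNA(times) || anyNA(dissolved))
    stop("missing values in `times` or `dissolved`", call. = FALSE)
  if (any(times < 0))
    stop("sampling times must be >= 0", call. = FALSE)
  if (any(diff(times) <= 0)) {
    bad <- which(diff(times) <= 0)[1L] + 1L
    stop(sprintf("sampling times must be strictly increasing (violated at point %d, t = %g)",
                 bad, times[bad]), call. = FALSE)
  }
  if (any(dissolved < 0))
    stop("percent dissolved must be >= 0", call. = FALSE)
  if (any(dissolved > 100))
    warning(sprintf("profile '%s' has %d point(s) above 100%% dissolved (max %.2f%%); retained as-is",
                    label, sum(dissolved > 100), max(dissolved)), call. = FALSE)
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) != length(times))
      stop("`sd` must match the length of `times`", call. = FALSE)
    if (any(sd < 0, na.rm = TRUE))
      stop("`sd` values must be >= 0", call. = FALSE)
  }
  if (!is.null(n_replicates)) {
    n_replicates <- as.integer(n_replicates)
    if (length(n_replicates) != 1L || is.na(n_replicates) || n_replicates < 1L)
      stop("`n_replicates` must be a single positive integer", call. = FALSE)
  }
  structure(list(label = as.character(label)[1L], times = times,
                 dissolved = dissolved, sd = sd,
                 n_replicates = n_replicates),
            class = "dissolution_profile")
}

#' @export
print.dissolution_profile <- function(x, ...) {
  cat(sprintf("<dissolution_profile> %s: %d points, t = %g..%g min, %.1f%% dissolved at t_last\n",
              x$label, length(x$times), min(x$times), max(x$times),
              x$dissolved[length(x$dissolved)]))
  invisible(x)
}

#' @export
as.data.frame.dissolution_profile <- function(x, ...) {
  d <- data.frame(time_min = x$times, dissolved = x$dissolved)
  if (!is.null(x$sd)) d$sd <- x$sd
  d
}

#' Plot a set of dissolution profiles
#'
#' @param x a `dissolution_profile`.
#' @param ... further profiles to overlay, then graphical arguments.
#' @export
plot.dissolution_profile <- function(x, ...) {
  dots <- list(...)
  extra <- Filter(function(e) inherits(e, "dissolution_profile"), dots)
  profs <- c(list(x), extra)
  ylim <- c(0, max(vapply(profs, function(p) max(p$dissolved), 0), 100))
  plot(x$times, x$dissolved, type = "b", pch = 16, ylim = ylim,
       xlab = "Time (min)", ylab = "Cumulative dissolved (%)")
  if (length(extra)) {
    for (i in seq_along(extra))
      lines(extra[[i]]$times, extra[[i]]$dissolved, type = "b",
            pch = 16, col = i + 1L)
    legend("bottomright", legend = vapply(profs, `[[`, "", "label"),
           col = seq_along(profs), lty = 1, pch = 16, bty = "n")
  }
  invisible(x)
}

#' Read dissolution profiles from CSV
#'
#' Expected format: comma-separated with a header row; the time column is
#' named `time_min`; every other column is a labelled percent-dissolved
#' series, except columns named `<label>_sd` which are attached to the
#' matching series as replicate standard deviations.
#'
#' @param path path to a CSV file.
#' @return named list of [dissolution_profile] objects, one per series.
#' @seealso [write_profiles()]
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE)
  if (!"time_min" %in% names(d))
    stop("profile CSV must have a 'time_min' column", call. = FALSE)
  if (anyNA(d)) {
    idx <- which(is.na(d), arr.ind = TRUE)
    cells <- apply(idx, 1L, function(r)
      sprintf("row %d, column '%s'", r[1L], names(d)[r[2L]]))
    stop("missing values in profile CSV at: ",
         paste(cells, collapse = "; "), call. = FALSE)
  }
  tm <- d$time_min
  if (any(diff(tm) <= 0)) {
    bad <- which(diff(tm) <= 0)[1L] + 1L
    stop(sprintf("time_min column is not strictly increasing at row %d (t = %g)",
                 bad, tm[bad]), call. = FALSE)
  }
  labels <- setdiff(names(d), "time_min")
  sd_cols <- labels[grepl("_sd$", labels)]
  series <- setdiff(labels, sd_cols)
  if (!length(series)) stop("no series columns in profile CSV", call. = FALSE)
  out <- lapply(series, function(lab) {
    sdc <- paste0(lab, "_sd")
    dissolution_profile(times = tm, dissolved = d[[lab]], label = lab,
                        sd = if (sdc %in% sd_cols) d[[sdc]] else NULL)
  })
  names(out) <- series
  out
}

#' Write dissolution profiles to CSV
#'
#' All profiles must share one time grid (the format is a single wide
#' table). Values are written at full precision; a round trip through
#' [read_profiles()] is lossless well beyond 6 decimals.
#'
#' @param profiles a `dissolution_profile` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  grids <- lapply(profiles, `[[`, "times")
  if (length(profiles) > 1L &&
      !all(vapply(grids[-1L], function(g) isTRUE(all.equal(g, grids[[1L]])), TRUE)))
    stop("all profiles must share the same time grid to be written as one CSV",
         call. = FALSE)
  d <- data.frame(time_min = grids[[1L]])
  for (p in profiles) {
    d[[p$label]] <- p$dissolved
    if (!is.null(p$sd)) d[[paste0(p$label, "_sd")]] <- p$sd
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align two profiles onto a common time grid
#'
#' Point-wise profile comparisons (the similarity factor in particular)
#' presume common sampling times. The default keeps only the shared times;
#' `method = "interpolate"` instead linearly interpolates `b` onto the part
#' of `a`'s grid covered by `b`'s range.
#'
#' @param a,b `dissolution_profile` objects.
#' @param method `"intersect"` (default) or `"interpolate"`.
#' @return list with elements `a`, `b` (profiles on the identical shared
#'   grid) and `dropped` (number of time points discarded across both).
#' @export
align_profiles <- function(a, b, method = c("intersect", "interpolate")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "dissolution_profile"),
            inherits(b, "dissolution_profile"))
  if (method == "intersect") {
    shared <- intersect(a$times, b$times)
    if (length(shared) < 3L)
      stop(sprintf("only %d shared time point(s); need >= 3 (consider method = \"interpolate\")",
                   length(shared)), call. = FALSE)
    shared <- sort(shared)
    ai <- match(shared, a$times); bi <- match(shared, b$times)
    dropped <- (length(a$times) - length(shared)) +
      (length(b$times) - length(shared))
    new_a <- suppress_over100(dissolution_profile(
      shared, a$dissolved[ai], a$label,
      sd = if (!is.null(a$sd)) a$sd[ai] else NULL))
    new_b <- suppress_over100(dissolution_profile(
      shared, b$dissolved[bi], b$label,
      sd = if (!is.null(b$sd)) b$sd[bi] else NULL))
  } else {
    grid <- a$times[a$times >= min(b$times) & a$times <= max(b$times)]
    if (length(grid) < 3L)
      stop("fewer than 3 of a's time points fall inside b's range",
           call. = FALSE)
    dropped <- length(a$times) - length(grid)
    new_a <- suppress_over100(dissolution_profile(
      grid, a$dissolved[match(grid, a$times)], a$label))
    new_b <- suppress_over100(dissolution_profile(
      grid, stats::approx(b$times, b$dissolved, xout = grid)$y, b$label))
  }
  list(a = new_a, b = new_b, dropped = dropped)
}

# re-validating an already-validated profile must not re-warn on >100%
suppress_over100 <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("above 100% dissolved", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Construct a generic (x, y) series
#'
#' Thin carrier for two-column tabular series: XRD patterns (degrees 2-theta
#' vs counts) and plasma concentration time courses (hours vs ug/mL).
#'
#' @param x strictly increasing abscissae.
#' @param y ordinates, same length as `x`.
#' @return object of class `xy_series` (a list with `x`, `y`).
#' @export
xy_series <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("`x` must be strictly increasing", call. = FALSE)
  structure(list(x = x, y = y), class = "xy_series")
}
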