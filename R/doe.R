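#' The 18-run diacerein solid-dispersion factorial design
#'
#' The I-optimal factorial design used to optimize diacerein solid
#' dispersions: two formulation factors — drug:polymer ratio (polymer
#' parts per drug part: 1, 2 or 4) and polymer type (PVP K25, PVP K90,
#' PEG 4000, PEG 8000) — with four measured responses per run: drug
#' content DC (%), dissolution efficiency at 15 and 60 min DE15/DE60 (%),
#' and mean dissolution time MDT (min). The similarity factor of each
#' system versus the plain drug is carried alongside. Six factor settings
#' are duplicated, providing the pure-error degrees of freedom needed for
#' a lack-of-fit test.
#'
#' @return data.frame with columns `run`, `ratio_parts`, `polymer`, `dc`,
#'   `de15`, `de60`, `mdt`, `f2`.
#' @export
diacerein_design <- function() {
  d <- data.frame(
    run = paste0("SD", 1:18),
    ratio_parts = c(1, 1, 2, 2, 4,  1, 1, 2, 2, 4,  1, 2, 2, 4,  1, 2, 2, 4),
    polymer = c(rep("PVP K25", 5), rep("PVP K90", 5),
                rep("PEG 4000", 4), rep("PEG 8000", 4)),
    dc   = c(95.52, 93.98, 93.99, 89.76, 96.00,
             92.61, 89.45, 93.59, 96.20, 96.52,
             93.13, 96.71, 100.68, 98.89,
             98.76, 92.47, 91.30, 98.01),
    de15 = c(35.23, 33.31, 52.71, 51.28, 28.57,
             31.79, 29.65, 13.69, 15.05, 36.98,
             39.29, 27.50, 27.37, 39.97,
             68.13, 46.57, 44.81, 78.35),
    de60 = c(75.66, 73.12, 71.66, 72.55, 76.97,
             63.13, 61.18, 40.03, 42.70, 67.33,
             54.82, 43.93, 41.95, 70.55,
             81.65, 77.08, 75.17, 95.92),
    mdt  = c(11.56, 12.55, 13.78, 12.86, 10.88,
             19.10, 20.88, 28.47, 26.81, 15.99,
             14.11, 16.52, 18.16, 16.04,
             8.12, 10.88, 11.60, 4.55),
    f2   = c(15.88, 17.61, 14.52, 15.67, 20.20,
             21.98, 23.07, 42.10, 39.36, 17.10,
             25.14, 35.77, 36.74, 18.18,
             10.64, 14.81, 15.70, 6.36),
    stringsAsFactors = FALSE)
  d$polymer <- factor(d$polymer,
                      levels = c("PVP K25", "PVP K90", "PEG 4000", "PEG 8000"))
  d
}

polymer_levels <- function(design) {
  if (is.factor(design$polymer)) levels(design$polymer)
  else sort(unique(design$polymer))
}

#' Encode a factorial design as a coded model matrix
#'
#' The numeric drug:polymer ratio factor is affinely scaled so its level
#' range maps to \[-1, +1\] (levels 1, 2, 4 code to -1, -1/3, +1); the
#' categorical polymer factor is expanded to sum-to-zero contrast columns
#' so the intercept estimates the grand mean, the response-surface ANOVA
#' convention. Model orders grow nested: `linear` has intercept + ratio +
#' 3 polymer contrasts; `2fi` adds the ratio-by-polymer interaction
#' products; `quadratic` adds the squared ratio term.
#'
#' With `ratio_as = "categorical"` the ratio is instead treated as a
#' 3-level factor (sum-to-zero contrasts); the quadratic order is then
#' unavailable.
#'
#' @param design data.frame with columns `ratio_parts` and `polymer`
#'   (see [diacerein_design()] for the packaged example).
#' @param model_order `"linear"`, `"2fi"` or `"quadratic"`.
#' @param ratio_as `"numeric"` (default) or `"categorical"`.
#' @param levels_ratio,levels_polymer admissible levels; default taken
#'   from the data. Supplying them explicitly fixes the coding so new
#'   settings (prediction candidates) encode identically.
#' @return numeric model matrix with an `(Intercept)` column; the coding
#'   metadata is attached as attribute `"coding"`.
#' @export
encode_design <- function(design,
                          model_order = c("linear", "2fi", "quadratic"),
                          ratio_as = c("numeric", "categorical"),
                          levels_ratio = NULL, levels_polymer = NULL) {
  model_order <- match.arg(model_order)
  ratio_as <- match.arg(ratio_as)
  stopifnot(is.data.frame(design),
            all(c("ratio_parts", "polymer") %in% names(design)))
  if (is.null(levels_ratio)) levels_ratio <- sort(unique(design$ratio_parts))
  if (is.null(levels_polymer)) levels_polymer <- polymer_levels(design)
  if (!all(design$ratio_parts %in% levels_ratio))
    stop("ratio_parts contains values outside the declared levels",
         call. = FALSE)
  if (!all(as.character(design$polymer) %in% levels_polymer))
    stop("polymer contains values outside the declared levels", call. = FALSE)

  n <- nrow(design)
  # categorical factor: sum-to-zero contrasts
  pf <- factor(as.character(design$polymer), levels = levels_polymer)
  CB <- stats::contr.sum(length(levels_polymer))
  B <- CB[as.integer(pf), , drop = FALSE]
  colnames(B) <- paste0("B", seq_len(ncol(B)))

  if (ratio_as == "numeric") {
    if (model_order == "quadratic" && length(levels_ratio) < 3L)
      stop("quadratic model requires >= 3 numeric ratio levels", call. = FALSE)
    rng <- range(levels_ratio)
    A <- 2 * (design$ratio_parts - rng[1L]) / diff(rng) - 1
    X <- cbind(`(Intercept)` = 1, A = A, B)
    if (model_order %in% c("2fi", "quadratic")) {
      AB <- A * B
      colnames(AB) <- paste0("A:", colnames(B))
      X <- cbind(X, AB)
    }
    if (model_order == "quadratic") X <- cbind(X, `A^2` = A^2)
  } else {
    if (model_order == "quadratic")
      stop("quadratic model is undefined for a categorical ratio factor",
           call. = FALSE)
    rf <- factor(design$ratio_parts, levels = levels_ratio)
    CA <- stats::contr.sum(length(levels_ratio))
    A <- CA[as.integer(rf), , drop = FALSE]
    colnames(A) <- paste0("A", seq_len(ncol(A)))
    X <- cbind(`(Intercept)` = 1, A, B)
    if (model_order == "2fi") {
      AB <- do.call(cbind, lapply(seq_len(ncol(A)), function(i) {
        M <- A[, i] * B
        colnames(M) <- paste0(colnames(A)[i], ":", colnames(B))
        M
      }))
      X <- cbind(X, AB)
    }
  }
  attr(X, "coding") <- list(model_order = model_order, ratio_as = ratio_as,
                            levels_ratio = levels_ratio,
                            levels_polymer = levels_polymer)
  X
}

#' Fit a response-surface model to one design response
#'
#' Ordinary least squares on the coded model matrix, with the full
#' response-surface diagnostic set:
#' \itemize{
#'   \item ANOVA partition of total SS into model and residual, and of the
#'     residual into lack-of-fit and pure error using replicate groups
#'     (runs sharing identical factor settings);
#'   \item \eqn{R^2}, adjusted \eqn{R^2};
#'   \item PRESS via the hat-matrix shortcut
#'     \eqn{\sum_i [e_i/(1-h_{ii})]^2} and predicted
#'     \eqn{R^2 = 1 - PRESS/SS_{tot}};
#'   \item adequate precision
#'     \eqn{(\max\hat y - \min\hat y)/\sqrt{p\,MSE/n}}, the
#'     signal-to-noise measure for which values above 4 indicate a model
#'     usable for navigation of the design space.
#' }
#'
#' @param design data.frame with `ratio_parts`, `polymer` and the response
#'   column.
#' @param response name of the response column.
#' @param model_order `"linear"`, `"2fi"` or `"quadratic"`.
#' @param ratio_as passed to [encode_design()].
#' @return object of class `response_model`.
#' @export
fit_response_model <- function(design, response,
                               model_order = c("linear", "2fi", "quadratic"),
                               ratio_as = c("numeric", "categorical")) {
  model_order <- match.arg(model_order)
  ratio_as <- match.arg(ratio_as)
  if (!response %in% names(design))
    stop("response column '", response, "' not in design", call. = FALSE)
  y <- design[[response]]
  if (anyNA(y)) stop("missing values in response '", response, "'",
                     call. = FALSE)
  X <- encode_design(design, model_order, ratio_as)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 1L)
    stop(sprintf("need at least %d runs for %d model terms", p + 1L, p),
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("singular coded matrix; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  e <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(e^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1L
  df_res <- n - p
  ms_res <- ss_res / df_res
  f_model <- (ss_mod / df_mod) / ms_res
  p_model <- stats::pf(f_model, df_mod, df_res, lower.tail = FALSE)

  # lack of fit vs pure error from replicate groups
  grp <- interaction(design$ratio_parts, design$polymer, drop = TRUE)
  ss_pe <- sum(tapply(y, grp, function(v) sum((v - mean(v))^2)))
  df_pe <- n - nlevels(grp)
  ss_lof <- ss_res - ss_pe
  df_lof <- df_res - df_pe
  if (df_pe > 0L && df_lof > 0L) {
    f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    p_lof <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
  } else {
    f_lof <- NA_real_; p_lof <- NA_real_
  }

  # leverage via the thin-Q factor
  Q <- qr.Q(qrX)
  h <- rowSums(Q^2)
  press <- sum((e / (1 - h))^2)

  r2 <- 1 - ss_res / ss_tot
  adj_r2 <- 1 - (ss_res / df_res) / (ss_tot / (n - 1L))
  pred_r2 <- 1 - press / ss_tot
  adeq_prec <- (max(fitted) - min(fitted)) / sqrt(p * ms_res / n)

  structure(list(
    response = response, model_order = model_order, ratio_as = ratio_as,
    coefficients = beta, fitted = fitted, residuals = e,
    coding = attr(X, "coding"), design = design, y = y,
    anova = list(ss_model = ss_mod, df_model = df_mod,
                 ss_residual = ss_res, df_residual = df_res,
                 f_model = f_model, p_model = p_model,
                 ss_lack_of_fit = ss_lof, df_lack_of_fit = df_lof,
                 ss_pure_error = ss_pe, df_pure_error = df_pe,
                 f_lack_of_fit = f_lof, p_lack_of_fit = p_lof),
    r2 = r2, adj_r2 = adj_r2, pred_r2 = pred_r2, press = press,
    adequate_precision = adeq_prec, leverage = h, n = n, p = p),
    class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("<response_model> %s (%s): R^2 = %.4f, adj = %.4f, pred = %.4f, PRESS = %.4g\n",
              x$response, x$model_order, x$r2, x$adj_r2, x$pred_r2, x$press))
  cat(sprintf("  model F = %.2f (p = %.3g); lack-of-fit p = %.3g; adequate precision = %.2f\n",
              x$anova$f_model, x$anova$p_model, x$anova$p_lack_of_fit,
              x$adequate_precision))
  invisible(x)
}

#' Predict a fitted response model at new factor settings
#'
#' @param object a `response_model`.
#' @param newdata data.frame with `ratio_parts` and `polymer`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.response_model <- function(object, newdata, ...) {
  cd <- object$coding
  X <- encode_design(newdata, cd$model_order, cd$ratio_as,
                     levels_ratio = cd$levels_ratio,
                     levels_polymer = cd$levels_polymer)
  drop(X %*% object$coefficients)
}

#' Table of model-selection statistics across responses
#'
#' @param models named list of `response_model` objects.
#' @return data.frame, one row per model.
#' @export
model_statistics <- function(models) {
  rows <- lapply(models, function(m)
    data.frame(response = m$response, model = m$model_order,
               p_model = m$anova$p_model,
               p_lack_of_fit = m$anova$p_lack_of_fit,
               r2 = m$r2, adj_r2 = m$adj_r2, pred_r2 = m$pred_r2,
               adequate_precision = m$adequate_precision, press = m$press,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Derringer-Suich desirability optimization over the design space
#'
#' Each response prediction is mapped to a desirability d in \[0, 1\] by a
#' linear ramp between bounds L and T (default: the observed response
#' minimum and maximum): for a maximized response d = (yhat - L)/(T - L),
#' for a minimized response the mirror, both clipped to \[0, 1\]. The
#' overall desirability is the geometric mean of the per-response d's
#' (importance weights all 1), evaluated exhaustively over every candidate
#' factor-level combination; the argmax is returned, ties broken by
#' candidate order (ratio levels within polymer levels, as in the design
#' run order).
#'
#' @param models named list of `response_model` objects fitted on the same
#'   design.
#' @param goals named character vector over the same responses, each
#'   `"maximize"` or `"minimize"`.
#' @param bounds optional named list of `c(L, T)` per response; default
#'   observed min/max.
#' @return object of class `desirability_result`: list with `best`
#'   (one-row data.frame of settings, predictions, D), `candidates`
#'   (full evaluation table), `goals`.
#' @export
desirability_optimize <- function(models, goals, bounds = NULL) {
  stopifnot(length(models) >= 1L, all(names(goals) %in% names(models)))
  responses <- names(goals)
  cd <- models[[responses[1L]]]$coding
  for (r in responses)
    if (!identical(models[[r]]$coding[c("levels_ratio", "levels_polymer")],
                   cd[c("levels_ratio", "levels_polymer")]))
      stop("all models must be fitted on the same design", call. = FALSE)
  goals <- vapply(goals, function(g)
    match.arg(g, c("maximize", "minimize")), "")

  cand <- expand.grid(ratio_parts = cd$levels_ratio,
                      polymer = cd$levels_polymer,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d_mat <- matrix(NA_real_, nrow(cand), length(responses),
                  dimnames = list(NULL, responses))
  pred_mat <- d_mat
  for (r in responses) {
    m <- models[[r]]
    b <- if (!is.null(bounds) && !is.null(bounds[[r]])) bounds[[r]]
         else range(m$y)
    if (diff(b) <= 0)
      stop("degenerate desirability bounds for response '", r, "'",
           call. = FALSE)
    yhat <- predict(m, cand)
    d <- if (goals[[r]] == "maximize") (yhat - b[1L]) / diff(b)
         else (b[2L] - yhat) / diff(b)
    d_mat[, r] <- pmin(1, pmax(0, d))
    pred_mat[, r] <- yhat
  }
  D <- apply(d_mat, 1L, function(d) prod(d)^(1 / length(d)))
  best_i <- which.max(D)
  colnames(pred_mat) <- paste0("pred_", responses)
  colnames(d_mat) <- paste0("d_", responses)
  candidates <- cbind(cand, pred_mat, d_mat, D = D)
  structure(list(best = candidates[best_i, , drop = FALSE],
                 candidates = candidates, goals = goals),
            class = "desirability_result")
}

#' @export
print.desirability_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("<desirability_result> optimum: ratio 1:%g, %s (D = %.3f)\n",
              b$ratio_parts, b$polymer, b$D))
  invisible(x)
}
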