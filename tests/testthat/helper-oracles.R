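# Independent oracles and fixture builders shared across the suite.

# seeded random monotone 6-point cumulative profile
rand_profile <- function(seed, n_points = 6L, t_max = 60) {
  set.seed(seed)
  times <- c(0, sort(runif(n_points - 1L, 1, t_max)))
  incr <- runif(n_points - 1L, 0, 30)
  dissolved <- c(0, cumsum(incr))
  dissolved <- dissolved / max(dissolved) * runif(1, 40, 100)
  dissolution_profile(times, dissolved, sprintf("rand%d", seed))
}

# midpoint rectangle-sum DE oracle on a dense sub-grid (independent of the
# trapezoid implementation: relies only on linear interpolation)
de_oracle <- function(profile, t_end, n_sub = 1e4) {
  tt <- profile$times; yy <- profile$dissolved
  if (tt[1L] > 0) { tt <- c(0, tt); yy <- c(0, yy) }
  dt <- t_end / n_sub
  mids <- (seq_len(n_sub) - 0.5) * dt
  100 * sum(approx(tt, yy, xout = mids)$y * dt) / (100 * t_end)
}

# rectangle-sum MDT oracle: increment-weighted mean time on a dense grid
mdt_oracle <- function(profile, n_sub = 1e4) {
  tt <- profile$times; yy <- profile$dissolved
  if (tt[1L] > 0) { tt <- c(0, tt); yy <- c(0, yy) }
  grid <- seq(0, max(tt), length.out = n_sub + 1L)
  m <- approx(tt, yy, xout = grid)$y
  dM <- diff(m)
  mids <- (grid[-1L] + grid[-length(grid)]) / 2
  sum(mids * dM) / sum(dM)
}

# explicit leave-one-out PRESS: refit with each run left out in turn
press_loo_oracle <- function(design, response, model_order) {
  n <- nrow(design)
  sum(vapply(seq_len(n), function(i) {
    fit <- fit_response_model(design[-i, , drop = FALSE], response,
                              model_order)
    (design[[response]][i] - predict(fit, design[i, , drop = FALSE]))^2
  }, 0))
}

# default fast-release / slow-release formulation pair and a fixed subject
default_subject <- function(...) {
  args <- list(body_weight = 81, gastric_emptying_rate = log(2) / 0.25,
               intestinal_transit_rate = 7 / 3.32, n_transit = 7L,
               ka = 1.2, F = 0.45)
  args[names(list(...))] <- list(...)
  do.call(subject_physiology, args)
}
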