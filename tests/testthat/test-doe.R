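des <- diacerein_design()
goals4 <- c(dc = "maximize", de15 = "maximize", de60 = "maximize",
            mdt = "minimize")

test_that("coded encoding has the documented levels and column counts", {
  X <- encode_design(des, "linear")
  expect_equal(ncol(X), 5)  # intercept + ratio + 3 polymer contrasts
  expect_equal(sort(unique(X[, "A"])), c(-1, -1/3, 1))
  expect_true(all(X[, "(Intercept)"] == 1))
  # sum-to-zero: contrast columns sum to zero over a balanced level sweep
  bal <- data.frame(ratio_parts = 1, polymer = levels(des$polymer))
  Xb <- encode_design(bal, "linear", levels_ratio = c(1, 2, 4))
  expect_equal(colSums(Xb[, c("B1", "B2", "B3")]), c(B1 = 0, B2 = 0, B3 = 0))

  expect_equal(ncol(encode_design(des, "2fi")), 8)
  expect_equal(ncol(encode_design(des, "quadratic")), 9)
  expect_error(encode_design(data.frame(ratio_parts = c(1, 4, 1, 4),
                                        polymer = c("a", "a", "b", "b")),
                             "quadratic"), ">= 3 numeric ratio levels")
  expect_equal(ncol(encode_design(des, "linear", ratio_as = "categorical")), 6)
  expect_error(encode_design(des, "quadratic", ratio_as = "categorical"),
               "categorical")
})

test_that("noiseless synthetic responses are interpolated exactly", {
  beta <- c(50, 8, -4, 2, 6, 1.5, -2, 0.5, 3)
  d <- gen_doe_dataset(beta, "quadratic", noise_sd = 0)
  fit <- fit_response_model(d, "y", "quadratic")
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$press, 1e-16)
  expect_equal(fit$pred_r2, 1, tolerance = 1e-8)
})

test_that("hat-matrix PRESS equals the explicit leave-one-out refit oracle", {
  for (s in 1:20) {
    order <- c("linear", "2fi", "quadratic")[1 + s %% 3]
    p <- ncol(encode_design(des, order))
    set.seed(s)
    beta <- rnorm(p, 0, 5)
    d <- gen_doe_dataset(beta, order, noise_sd = 2, seed = s + 100)
    fit <- fit_response_model(d, "y", order)
    expect_equal(fit$press, press_loo_oracle(d, "y", order),
                 tolerance = 1e-8)
    expect_equal(fit$pred_r2,
                 1 - press_loo_oracle(d, "y", order) /
                   sum((d$y - mean(d$y))^2), tolerance = 1e-8)
  }
})

test_that("R^2 ordering and ANOVA bookkeeping hold on real responses", {
  for (r in c("dc", "de15", "de60", "mdt")) {
    for (order in c("linear", "quadratic")) {
      fit <- fit_response_model(des, r, order)
      expect_gte(fit$r2, fit$adj_r2)
      expect_gte(fit$r2, fit$pred_r2)
      expect_gte(fit$press, 0)
      expect_gte(fit$adequate_precision, 0)
      an <- fit$anova
      expect_equal(an$ss_model + an$ss_residual,
                   sum((des[[r]] - mean(des[[r]]))^2))
      expect_equal(an$ss_lack_of_fit + an$ss_pure_error, an$ss_residual)
      expect_equal(an$df_pure_error, 6)  # six duplicated settings
    }
  }
  # nesting: adding terms never decreases R^2
  expect_gte(fit_response_model(des, "de60", "quadratic")$r2,
             fit_response_model(des, "de60", "2fi")$r2)
  expect_gte(fit_response_model(des, "de60", "2fi")$r2,
             fit_response_model(des, "de60", "linear")$r2)
})

test_that("adjusted R^2 penalizes pure-noise terms on most seeded datasets", {
  p_lin <- ncol(encode_design(des, "linear"))
  drops <- logical(60)
  for (s in seq_along(drops)) {
    set.seed(s)
    beta <- c(rnorm(p_lin, 0, 5))
    d <- gen_doe_dataset(beta, "linear", noise_sd = 3, seed = s + 500)
    lin <- fit_response_model(d, "y", "linear")
    qua <- fit_response_model(d, "y", "quadratic")  # extra terms are noise
    drops[s] <- qua$adj_r2 < lin$adj_r2
  }
  expect_gt(mean(drops), 0.5)
})

test_that("aliased columns are reported, not silently dropped", {
  sub <- des[des$polymer %in% c("PVP K25", "PEG 8000"), ]
  expect_error(fit_response_model(sub, "dc", "linear"), "aliased")
})

test_that("coefficient estimates are unbiased under noise", {
  p_lin <- ncol(encode_design(des, "linear"))
  beta <- c(60, 5, -3, 1, 2)
  est <- matrix(NA_real_, 200, p_lin)
  for (s in 1:200)
    est[s, ] <- fit_response_model(
      gen_doe_dataset(beta, "linear", noise_sd = 2, seed = s), "y",
      "linear")$coefficients
  mc_se <- 2 / sqrt(200)  # generous bound: coded-matrix leverage < 1
  expect_true(all(abs(colMeans(est) - beta) < 4 * mc_se))
})

test_that("desirability optimization finds the fast-dissolving PEG 8000 system", {
  orders <- list(dc = "quadratic", de15 = "linear", de60 = "quadratic",
                 mdt = "quadratic")
  models <- lapply(setNames(nm = names(goals4)), function(r)
    fit_response_model(des, r, orders[[r]]))
  opt <- desirability_optimize(models, goals4)
  expect_equal(opt$best$ratio_parts, 4)
  expect_equal(opt$best$polymer, "PEG 8000")
  expect_equal(nrow(opt$candidates), 12)
  expect_true(all(opt$candidates$D >= 0 & opt$candidates$D <= 1))

  # order of responses must not matter
  opt_rev <- desirability_optimize(models[rev(names(goals4))],
                                   goals4[rev(names(goals4))])
  expect_equal(opt_rev$best$D, opt$best$D)
  expect_equal(opt_rev$best$polymer, opt$best$polymer)

  # the same optimum is found when the ratio is treated as categorical
  models_cat <- lapply(setNames(nm = names(goals4)), function(r)
    fit_response_model(des, r, "2fi", ratio_as = "categorical"))
  opt_cat <- desirability_optimize(models_cat, goals4)
  expect_equal(opt_cat$best$polymer, "PEG 8000")
  expect_equal(opt_cat$best$ratio_parts, 4)
})

test_that("desirability geometry: hand-set ramps give the geometric mean", {
  # single response, maximize: optimum is the setting with highest prediction
  m <- fit_response_model(des, "de60", "quadratic")
  opt1 <- desirability_optimize(list(de60 = m), c(de60 = "maximize"))
  preds <- predict(m, opt1$candidates[, c("ratio_parts", "polymer")])
  expect_equal(opt1$best$pred_de60, max(preds))

  # two responses with d = 0.25 and 1.0 combine to D = 0.5
  opt2 <- desirability_optimize(
    list(de60 = m, mdt = fit_response_model(des, "mdt", "quadratic")),
    c(de60 = "maximize", mdt = "minimize"))
  i <- which.max(opt2$candidates$D)
  expect_equal(opt2$candidates$D[i],
               sqrt(prod(opt2$candidates[i, c("d_de60", "d_mdt")])))
  expect_equal(sqrt(0.25 * 1.0), 0.5)

  expect_error(desirability_optimize(list(de60 = m), c(de60 = "maximize"),
                                     bounds = list(de60 = c(50, 50))),
               "degenerate")
})

test_that("the packaged design matches its printed structure", {
  expect_equal(nrow(des), 18)
  expect_equal(levels(des$polymer),
               c("PVP K25", "PVP K90", "PEG 4000", "PEG 8000"))
  expect_equal(sort(unique(des$ratio_parts)), c(1, 2, 4))
  sd18 <- des[des$run == "SD18", ]
  expect_equal(sd18$de15, 78.35)
  expect_equal(sd18$mdt, 4.55)
  expect_equal(sd18$f2, 6.36)
  # replicate structure: six duplicated settings
  grp <- interaction(des$ratio_parts, des$polymer, drop = TRUE)
  expect_equal(sum(table(grp) - 1), 6)
})
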