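grid7 <- c(0, 5, 10, 15, 30, 45, 60)

test_that("f2 hits its closed-form anchors and is symmetric", {
  ref <- gen_dissolution_profile("first_order", k = 0.05, times = grid7)
  expect_identical(similarity_factor(ref, ref), 100)

  off <- suppressWarnings(dissolution_profile(grid7, ref$dissolved + 10, "off"))
  f2_gap <- 50 * log10(100 / sqrt(101))
  expect_equal(similarity_factor(ref, off), f2_gap, tolerance = 1e-10)
  expect_equal(similarity_factor(off, ref), similarity_factor(ref, off))

  # strictly decreasing as any single point-wise gap grows
  scores <- sapply(c(2, 5, 10, 20), function(g) {
    d <- ref$dissolved; d[4] <- d[4] + g
    similarity_factor(ref, suppressWarnings(dissolution_profile(grid7, d, "g")))
  })
  expect_true(all(diff(scores) < 0))

  misaligned <- dissolution_profile(grid7 + 1, ref$dissolved, "m")
  expect_error(similarity_factor(ref, misaligned), "align_profiles")
})

test_that("f2 point-handling options behave as documented", {
  ref <- dissolution_profile(grid7, c(0, 20, 45, 70, 88, 95, 98), "r")
  tst <- dissolution_profile(grid7, c(0, 35, 60, 82, 89, 95.5, 98), "t")
  full <- similarity_factor(ref, tst)
  trunc <- similarity_factor(ref, tst, truncate_85 = TRUE)
  expect_lt(trunc, full)  # dropping the near-identical plateau leaves the
                          # early divergence to dominate
  with_zero <- similarity_factor(ref, tst, exclude_zero = FALSE)
  expect_gt(with_zero, full)  # the (0,0) point only dilutes the difference
})

test_that("dissolution efficiency matches geometry and the rectangle oracle", {
  instant <- dissolution_profile(c(0, 30, 60), c(100, 100, 100), "instant")
  expect_equal(dissolution_efficiency(instant, 60), 100)

  lin <- dissolution_profile(c(0, 60), c(0, 100), "linear")
  expect_equal(dissolution_efficiency(lin, 60), 50)

  # inserting a redundant collinear point changes nothing
  lin2 <- dissolution_profile(c(0, 30, 60), c(0, 50, 100), "linear2")
  expect_equal(dissolution_efficiency(lin2, 60),
               dissolution_efficiency(lin, 60))

  # t_end between sampling points: interpolated, not extrapolated
  expect_equal(dissolution_efficiency(lin, 45), dissolution_efficiency(lin, 45))
  expect_error(dissolution_efficiency(lin, 90), "extrapolation|beyond")

  for (s in 1:25) {
    p <- rand_profile(s)
    t_end <- max(p$times) * 0.8
    expect_equal(dissolution_efficiency(p, t_end), de_oracle(p, t_end),
                 tolerance = 5e-3)
  }
})

test_that("MDT matches its discrete definition and the continuous limit", {
  one <- dissolution_profile(c(10, 20), c(0, 100), "one")
  expect_equal(mean_dissolution_time(one), 15)

  eq <- dissolution_profile(c(0, 10, 20, 40), c(0, 30, 60, 90), "eq")
  expect_equal(mean_dissolution_time(eq), mean(c(5, 15, 30)))

  fine <- gen_dissolution_profile("first_order", k = 0.1,
                                  times = seq(0, 120, by = 0.25))
  expect_equal(mean_dissolution_time(fine), 10, tolerance = 0.02)

  # delaying all dissolution by delta increases MDT by exactly delta
  p <- rand_profile(42)
  delta <- 7.5
  shifted <- dissolution_profile(c(0, delta, p$times[-1] + delta),
                                 c(0, 0, p$dissolved[-1]), "sh")
  expect_equal(mean_dissolution_time(shifted),
               mean_dissolution_time(p) + delta, tolerance = 1e-10)

  flat <- dissolution_profile(c(0, 10, 20), c(0, 0, 0), "flat")
  expect_error(mean_dissolution_time(flat), "no dissolution")

  for (s in 26:50) {
    p <- rand_profile(s)
    expect_equal(mean_dissolution_time(p), mdt_oracle(p), tolerance = 5e-3)
  }
})

test_that("noisy decreases warn and the monotonize pre-pass restores order", {
  noisy <- dissolution_profile(c(0, 5, 10, 15, 30, 60),
                               c(0, 20, 18, 35, 60, 90), "noisy")
  expect_warning(mean_dissolution_time(noisy), "decreases")
  mono <- monotonize_profile(noisy)
  expect_true(all(diff(mono$dissolved) >= 0))
  expect_silent(mean_dissolution_time(mono))
  expect_lte(dissolution_efficiency(mono, 15), dissolution_efficiency(mono, 60))
})

test_that("fold change reproduces the headline gains and validates input", {
  expect_equal(as.numeric(fold_change(76.35, 7.05)), 10.83)
  expect_equal(as.numeric(fold_change(96.89, 28.30)), 3.42)
  expect_equal(as.numeric(fold_change(3.7, 3.7)), 1)
  expect_equal(attr(fold_change(76.35, 7.05), "raw"), 76.35 / 7.05)
  expect_error(fold_change(5, 0), "> 0")
})

test_that("the summary table assembles DE, MDT and f2 per system", {
  plain <- gen_dissolution_profile("first_order", k = 0.012, times = grid7,
                                   label = "plain")
  fast <- gen_dissolution_profile("first_order", k = 0.449, times = grid7,
                                  label = "SD18")
  tab <- dissolution_summary(list(plain, fast), reference = "plain")
  expect_equal(tab$label, c("plain", "SD18"))
  expect_true(is.na(tab$f2_vs_reference[1]))
  expect_lt(tab$f2_vs_reference[2], 50)
  expect_true(all(tab$de15 <= tab$de60))
  expect_gt(tab$mdt[1], tab$mdt[2])
  expect_error(dissolution_summary(list(plain), reference = "nope"),
               "not found")
})
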