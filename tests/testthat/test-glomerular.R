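test_that("relational normalization fixes the mean and is scale invariant", {
  expect_equal(normalize_columns(rep(0.7, 6), target_mean = 0.2), rep(0.2, 6))
  v <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(normalize_columns(v, 0.25), v)  # mean already 0.25
  for (s in c(0.01, 0.5, 10, 300)) {
    expect_equal(normalize_columns(v * s, 0.25), normalize_columns(v, 0.25))
  }
  out <- normalize_columns(c(0, 0.05, 0.1), 0.25)
  expect_equal(mean(out), 0.25)
})

test_that("all-zero input is flagged as a blank scene, overflow is clipped or rescaled", {
  z <- normalize_columns(numeric(8), 0.25)
  expect_equal(as.numeric(z), numeric(8))
  expect_true(isTRUE(attr(z, "blank_scene")))
  skew <- c(1, rep(0.01, 9))
  expect_warning(h <- normalize_columns(skew, 0.5, clip = "hard"), "clipped")
  expect_lte(max(h), 1)
  s <- normalize_columns(skew, 0.5, clip = "soft")
  expect_equal(max(s), 1)
  # soft mode preserves ratios between columns
  expect_equal(s[2] / s[1], skew[2] / skew[1])
})

test_that("contrast enhancement reproduces the closed-form excited / inhibited / silent partition", {
  expect_equal(ntce_transform(0), 0)
  expect_equal(ntce_transform(0.15), 0.15 - 0.5 * 0.0225 / 0.0625)  # -0.03
  expect_equal(ntce_transform(0.8), 0.8 - 0.5 * 0.64 / 0.68)        # ~0.329
  f <- ntce_transform(seq(0, 1, by = 0.005))
  # inhibition dominates on an interval of moderate input, excitation above
  expect_true(any(f < 0))
  expect_gt(ntce_transform(0.5), 0)
  expect_gt(ntce_transform(1), 0)
  # crossover of the default parameterization: roots at x = 0.1 and 0.4
  expect_equal(ntce_transform(0.1), 0, tolerance = 1e-12)
  expect_equal(ntce_transform(0.4), 0, tolerance = 1e-12)
  expect_lt(ntce_transform(0.25), 0)
})

test_that("contrast enhancement is order preserving and stringency scales inhibition", {
  # order preserving on the excited set (above the 0.4 crossover); within
  # the suppression band the response dips below baseline non-monotonically
  x <- seq(0.41, 1, by = 0.005)
  expect_true(all(diff(ntce_transform(x)) > 0))
  x <- seq(0.01, 1, by = 0.01)
  expect_equal(ntce_transform(x, ntce_params(stringency = 0)), x)
  g2 <- ntce_params(excitation_gain = 2, stringency = 0)
  expect_equal(ntce_transform(x, g2), 2 * x)
  # higher stringency inhibits more at every nonzero input
  lo <- ntce_transform(x, ntce_params(stringency = 0.5))
  hi <- ntce_transform(x, ntce_params(stringency = 2))
  expect_true(all(hi < lo))
})

test_that("probe column shows excitation / surround inhibition / indifference along a similarity series", {
  # 6-column toy; affinity means are exactly the normalization target so the
  # probe sees precisely 0.9 (preferred), 0.3 (near neighbor), 0.05 (distant)
  series <- list(
    c(0.90, 0.30, 0.15, 0.10, 0.03, 0.02),
    c(0.30, 0.90, 0.15, 0.10, 0.03, 0.02),
    c(0.05, 0.10, 0.90, 0.40, 0.03, 0.02)
  )
  resp <- surround_profile(1, series)
  expect_gt(resp[1], 0)                 # preferred: excited
  expect_lt(resp[2], 0)                 # near neighbor: below baseline
  expect_lt(abs(resp[3]), 0.05)         # distant: essentially silent
  expect_equal(resp[1], ntce_transform(0.9))
  expect_equal(resp[2], ntce_transform(0.3))
  expect_error(surround_profile(1, series[1:2]), "3 odors")
})

test_that("pipeline has no dependence on column order", {
  sig <- make_signature(24, 0.5, seed = 4)
  cfg <- bulb_config(scene = list(n_receptors = 24L), seed = 1)
  perm <- c(13:24, 1:12)
  p <- as.integer(present_odor(sig, cfg))
  pp <- as.integer(present_odor(sig$affinity[perm], cfg))
  expect_identical(pp, p[perm])
})
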