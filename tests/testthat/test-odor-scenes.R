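test_that("signatures have exact support size, range, and are seed-reproducible", {
  cases <- list(c(n = 4, sp = 1.0, k = 4), c(n = 72, sp = 0.5, k = 36),
                c(n = 4, sp = 0.25, k = 1), c(n = 36, sp = 0.1, k = 4))
  for (cs in cases) {
    sig <- make_signature(cs["n"], cs["sp"], seed = 11)
    expect_length(sig$affinity, cs["n"])
    expect_equal(sum(sig$affinity > 0), unname(cs["k"]))
    expect_true(all(sig$affinity >= 0 & sig$affinity <= 1))
    expect_true(all(sig$affinity[sig$affinity > 0] > 0))
    sig2 <- make_signature(cs["n"], cs["sp"], seed = 11)
    expect_identical(sig$affinity, sig2$affinity)
  }
  expect_error(make_signature(72, 0), "sparsity")
  expect_error(make_signature(72, -0.1), "sparsity")
})

test_that("occlusion replaces exactly round(fN) channels and leaves the rest bit-identical", {
  p <- make_signature(72, 0.5, seed = 3)$affinity
  expect_identical(apply_bernoulli_occlusion(p, 0, seed = 1), p)
  for (f in c(0.25, 0.5, 0.6)) {
    q <- apply_bernoulli_occlusion(p, f, seed = 1)
    changed <- which(q != p)
    expect_length(changed, round(f * 72))
    expect_identical(q[-changed], p[-changed])  # bitwise
    expect_true(all(q >= 0 & q <= 1))
  }
  # determinism: same seed/index gives identical draws; different index differs
  expect_identical(apply_bernoulli_occlusion(p, 0.5, seed = 9, index = 2),
                   apply_bernoulli_occlusion(p, 0.5, seed = 9, index = 2))
  expect_false(identical(apply_bernoulli_occlusion(p, 0.5, seed = 9, index = 2),
                         apply_bernoulli_occlusion(p, 0.5, seed = 9, index = 3)))
})

test_that("full occlusion of a zero pattern has mean 1/2 (uniform replacement)", {
  # oracle: replacements are U(0,1), so the mean over many draws is 0.5;
  # 3 standard errors with 1000 draws x 72 channels
  m <- mean(vapply(1:1000, function(i) {
    mean(apply_bernoulli_occlusion(numeric(72), 1, seed = 500, index = i))
  }, 1.0))
  se <- sqrt(1 / 12) / sqrt(1000 * 72)
  expect_lt(abs(m - 0.5), 3 * se)
})

test_that("plume noise is multiplicative, zero-preserving, and mean-preserving at moderate sigma", {
  p <- rep(0.5, 72)
  expect_identical(apply_plume_noise(p, 0, seed = 1), p)
  expect_identical(apply_plume_noise(numeric(72), 0.3, seed = 1), numeric(72))
  expect_error(apply_plume_noise(p, -1), "sigma")
  # truncation/clipping are negligible at sigma = 0.2 around 0.5, so the
  # Monte Carlo mean stays within [0.49, 0.51]
  m <- mean(vapply(1:140, function(i) {
    mean(apply_plume_noise(p, 0.2, seed = 77, index = i))
  }, 1.0))
  expect_gt(m, 0.49)
  expect_lt(m, 0.51)
  out <- apply_plume_noise(rep(0.95, 100), 0.5, seed = 1)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("mixture rules reduce correctly in their limit and closed-form cases", {
  a <- make_signature(4, 0.5, seed = 1, id = "a")
  # single odor, competitive, c >> K saturates to the odor's own affinity
  expect_equal(mix_scenes(list(a), 1e8, rule = "competitive", K = 1),
               a$affinity, tolerance = 1e-7)
  # two identical signatures at weights 0.5/0.5 under sum-saturate = the odor
  expect_equal(mix_scenes(list(a, a), c(0.5, 0.5), rule = "sum-saturate"),
               a$affinity)
  # orthogonal supports, competitive, equal concentrations:
  # drive = affinity * c / (K + 2c), hand arithmetic on 4 receptors
  s1 <- c(0.5, 0, 0.8, 0); s2 <- c(0, 0.3, 0, 0.9)
  got <- mix_scenes(list(s1, s2), c(2, 2), rule = "competitive", K = 1)
  expect_equal(got, (s1 + s2) * 2 / (1 + 4))
  expect_error(mix_scenes(list(s1, s2), 1), "length")
  expect_error(mix_scenes(list(s1), 0), "positive")
})

test_that("scene CSV dialect round-trips", {
  sc <- rbind(make_signature(8, 0.5, seed = 1)$affinity,
              make_signature(8, 0.5, seed = 2)$affinity)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scenes(sc, path, odor_id = c("x", "y"), concentration = 1,
               occlusion_fraction = 0.5, seed = 42L)
  back <- read_scenes(path)
  expect_equal(unname(back$channels), unname(sc), tolerance = 1e-12)
  expect_identical(back$meta$odor_id, c("x", "y"))
  expect_identical(colnames(back$channels)[1], "channel_000")
})
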