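test_that("gamma closed forms hold on uniform fields", {
  ref <- dose_plane(matrix(2, 10, 10), c(0.2, 0.2))
  # identical planes: gamma identically 0, 100% pass
  g0 <- gamma_index(ref, ref)
  expect_true(all(g0$gamma_map == 0))
  expect_equal(g0$pass_rate, 100)
  # uniform +5% with DD 4%: dose term only, gamma = 0.05/0.04 = 1.25
  g5 <- gamma_index(ref, dose_plane(matrix(2 * 1.05, 10, 10), c(0.2, 0.2)),
                    dd = 4, dta = 0.3)
  expect_equal(unname(range(g5$gamma_map)), c(1.25, 1.25), tolerance = 1e-12)
  expect_equal(g5$pass_rate, 0)
  expect_error(gamma_index(ref, ref, dd = 0), "positive")
})

test_that("a pure translation by one DTA passes everywhere", {
  ref <- smooth_plane(31, n = 14)
  # same dose field, origin shifted by exactly one DTA along x; pad the target
  # extent so every reference pixel can see its displaced twin
  tgt <- dose_plane(ref$values, ref$spacing, ref$origin + c(0.3, 0))
  g <- gamma_index(ref, tgt, dd = 4, dta = 0.3)
  expect_true(all(g$gamma_map[!is.na(g$gamma_map)] <= 1 + 1e-9))
})

test_that("gamma maps match an exhaustive fine-sampling oracle within 0.02", {
  for (seed in c(3, 8)) {
    ref <- smooth_plane(seed)
    tgt <- perturbed_target(ref, seed + 500)
    g <- gamma_index(ref, tgt, dd = 4, dta = 0.3, eval_threshold = 10)
    o <- gamma_oracle(ref, tgt, dd = 4, dta = 0.3, thr = 10)
    expect_lt(max(abs(g$gamma_map - o), na.rm = TRUE), 0.02)
  }
})

test_that("gamma is invariant under common rescaling and monotone in the criteria", {
  ref <- smooth_plane(12, n = 10)
  tgt <- perturbed_target(ref, 13, amp = 0.05)
  g1 <- gamma_index(ref, tgt)
  gs <- gamma_index(dose_plane(ref$values * 3.7, ref$spacing, ref$origin),
                    dose_plane(tgt$values * 3.7, tgt$spacing, tgt$origin))
  expect_equal(gs$gamma_map, g1$gamma_map, tolerance = 1e-9)
  # loosening either criterion never lowers the pass rate
  base <- gamma_index(ref, tgt, dd = 2, dta = 0.2)
  expect_gte(gamma_index(ref, tgt, dd = 4, dta = 0.2)$pass_rate, base$pass_rate)
  expect_gte(gamma_index(ref, tgt, dd = 2, dta = 0.4)$pass_rate, base$pass_rate)
})

test_that("non-overlapping planes are rejected", {
  ref <- dose_plane(matrix(1, 5, 5), c(0.2, 0.2), origin = c(0, 0))
  far <- dose_plane(matrix(1, 5, 5), c(0.2, 0.2), origin = c(100, 100))
  expect_error(gamma_index(ref, far), "overlap")
})

test_that("masked difference statistics follow their arithmetic", {
  ref <- smooth_plane(40, n = 12)
  expect_equal(masked_diff_stats(ref, ref)$max_rel_diff, 0)
  # constant absolute offset of 2% of max: the largest relative difference
  # sits at the mask's minimum-dose pixel
  off <- 0.02 * max(ref$values)
  tgt <- dose_plane(ref$values + off, ref$spacing, ref$origin)
  s <- masked_diff_stats(ref, tgt, isodose_level = 80)
  expect_equal(s$max_rel_diff, off / min(ref$values[ref$values >= 0.8 * max(ref$values)]) * 100)
  expect_lte(s$mean_rel_diff, s$max_rel_diff)
  expect_equal(s$max_abs_diff, off)
  # a mask holding a single pixel forces mean = max
  s1 <- masked_diff_stats(ref, tgt, isodose_level = 99.99)
  expect_equal(s1$n_pixels, 1)
  expect_equal(s1$mean_rel_diff, s1$max_rel_diff)
  expect_error(masked_diff_stats(ref, dose_plane(matrix(1, 2, 2), c(0.2, 0.2),
                                                 origin = c(50, 50))), "empty")
})

test_that("differing geometries are handled by resampling the target only", {
  ref <- smooth_plane(50, n = 12, sp = 0.2)
  # finer target sampling of the same continuous field
  set.seed(50)
  x <- (0:23) * 0.1
  g <- expand.grid(x = x, y = x)
  v <- rep(0.15, nrow(g))
  for (k in 1:3) {
    cx <- runif(1, 1, 3); cy <- runif(1, 1, 3)
    a <- runif(1, 0.4, 0.8); s <- runif(1, 1.2, 2.0)
    v <- v + a * exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * s^2))
  }
  tgt <- dose_plane(matrix(v, 24, 24), c(0.1, 0.1))
  s <- masked_diff_stats(ref, tgt, isodose_level = 50)
  expect_lt(s$max_rel_diff, 0.5)  # same field, only interpolation error
  g1 <- gamma_index(ref, tgt)
  expect_equal(g1$pass_rate, 100)
})

test_that("dose-plane CSV round-trips values and geometry", {
  ref <- smooth_plane(60, n = 9)
  p <- withr::local_tempfile(fileext = ".csv")
  write_dose_csv(ref, p)
  back <- read_dose_csv(p)
  expect_equal(back$values, ref$values, tolerance = 1e-12)
  expect_equal(back$spacing, ref$spacing)
  expect_equal(back$origin, ref$origin)
})
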