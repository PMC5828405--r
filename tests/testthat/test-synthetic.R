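test_that("phantom rasterization honors geometry and precedence", {
  # a z-axis cylinder of radius 2 voxels in a 9^3 unit grid: label count is
  # the discrete disk size times the height
  spec <- phantom_spec(dim = c(9, 9, 9), spacing = c(1, 1, 1),
                       regions = tibble::tibble(material = "water", shape = "cylinder",
                                                cx = 4, cy = 4, cz = 4,
                                                rx = 2, ry = 2, rz = 2))
  truth <- rasterize_phantom(spec)
  xs <- 0:8
  disk <- sum(outer((xs - 4)^2, (xs - 4)^2, "+") <= 4)
  height <- sum(abs(xs - 4) <= 2)
  expect_equal(sum(truth$labels == 1), disk * height)
  # empty region list: all background
  empty <- phantom_spec(dim = c(4, 4, 4), regions = NULL, background = "air")
  expect_true(all(rasterize_phantom(empty)$labels == 0))
  # later regions overwrite earlier ones
  two <- phantom_spec(dim = c(10, 10, 4), spacing = c(1, 1, 1),
                      regions = tibble::tibble(
                        material = c("water", "muscle"), shape = "box",
                        cx = c(3, 5), cy = c(5, 5), cz = c(1.5, 1.5),
                        rx = c(3, 3), ry = c(3, 3), rz = c(2, 2)))
  t2 <- rasterize_phantom(two)
  expect_equal(unname(t2$labels[6, 6, 1]), t2$legend$label[t2$legend$name == "muscle"])
})

test_that("default phantoms are well-formed and deterministic", {
  ph <- make_default_phantoms()
  expect_named(ph, c("cylinders", "mouse"))
  expect_equal(length(unique(ph$cylinders$regions$material)), 8)
  expect_true(all(c("soft_tissue_male", "lung_inflated", "femur") %in%
                    ph$mouse$regions$material))
  # both rasterize without error on the default 0.2 mm grid
  t1 <- rasterize_phantom(ph$cylinders)
  t2 <- rasterize_phantom(ph$mouse)
  expect_gt(sum(t1$labels > 0), 0)
  expect_gt(sum(t2$labels > 0), 0)
  expect_identical(rasterize_phantom(ph$mouse)$labels, t2$labels)
})

test_that("the forward HU model is exact without noise and reproducible with it", {
  ph <- make_default_phantoms(spacing = c(0.5, 0.5, 0.5))$cylinders
  truth <- rasterize_phantom(ph)
  curve <- default_hu_curve()
  v0 <- simulate_hu(truth, icru_rho_zeff(), curve, sigma = 0)
  rz <- icru_rho_zeff()
  for (lab in truth$legend$label) {
    nm <- truth$legend$name[truth$legend$label == lab]
    expect_true(all(v0$values[truth$labels == lab] ==
                      predict_hu(curve, rz$rho_zeff[rz$name == nm])))
  }
  expect_true(all(v0$values[truth$labels == 0] == -1000))
  va <- simulate_hu(truth, rz, curve, sigma = 10, seed = 42)
  vb <- simulate_hu(truth, rz, curve, sigma = 10, seed = 42)
  expect_identical(va$values, vb$values)
  vc <- simulate_hu(truth, rz, curve, sigma = 10, seed = 43)
  expect_false(identical(va$values, vc$values))
  expect_error(simulate_hu(truth, rz[-1, ], curve), "rho_zeff known|No rho_zeff")
})

test_that("phantom YAML specs round-trip", {
  ph <- make_default_phantoms()$mouse
  p <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_yaml(ph, p)
  back <- read_phantom_yaml(p)
  expect_equal(back$dim, ph$dim)
  expect_equal(back$spacing, ph$spacing)
  expect_equal(as.data.frame(back$regions), as.data.frame(ph$regions))
  expect_identical(back$background, ph$background)
})
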