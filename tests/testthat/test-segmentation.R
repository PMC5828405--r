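test_that("MetaImage volumes round-trip exactly and reject truncated payloads", {
  set.seed(21)
  v <- image_volume(array(as.numeric(sample(-1000:3000, 4 * 5 * 6, TRUE)), c(4, 5, 6)),
                    spacing = c(0.2, 0.2, 0.4), origin = c(1, -2, 3))
  p <- file.path(withr::local_tempdir(), "vol.mhd")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_identical(v2$values, v$values)
  expect_equal(v2$spacing, c(0.2, 0.2, 0.4))   # anisotropic spacing preserved
  expect_equal(v2$origin, c(1, -2, 3))
  # truncate the raw payload
  raw <- sub("\\.mhd$", ".raw", p)
  writeBin(readBin(raw, "raw", 10), raw)
  expect_error(read_volume(p), "Truncated")
  expect_error(read_volume("nope.mhd"), "No such file")
})

test_that("NIfTI volumes round-trip values and geometry", {
  v <- image_volume(array(rnorm(3 * 4 * 5), c(3, 4, 5)),
                    spacing = c(0.3, 0.3, 0.6), origin = c(5, 6, 7))
  p <- file.path(withr::local_tempdir(), "vol.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_equal(v2$values, v$values, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(v2$origin, v$origin, tolerance = 1e-5)
})

test_that("uniform volumes segment to the expected tissue or to air", {
  db <- build_tissue_db()
  hu78 <- predict_hu(db$curve, 7.8)
  vol <- image_volume(array(hu78, c(5, 5, 5)))
  lab <- segment_volume(vol, db)
  expect_true(all(lab$labels == which(db$tissues$target_rho_zeff == 7.8)))
  air <- image_volume(array(-1000, c(4, 4, 4)))
  expect_true(all(segment_volume(air, db, air_threshold = -900)$labels == 0))
  expect_error(segment_volume(image_volume(array(0, c(0, 1, 1))), db), "Empty")
})

test_that("segmentation is a pure per-voxel map: idempotent, order-independent, count-preserving", {
  db <- build_tissue_db()
  set.seed(5)
  hu <- array(runif(6 * 6 * 6, -1100, 3000), c(6, 6, 6))
  vol <- image_volume(hu)
  l1 <- segment_volume(vol, db)
  l2 <- segment_volume(vol, db)
  expect_identical(l1$labels, l2$labels)
  expect_length(l1$labels, length(hu))
  perm <- sample(length(hu))
  lp <- segment_volume(image_volume(array(hu[perm], dim(hu))), db)
  expect_identical(as.vector(lp$labels), as.vector(l1$labels)[perm])
})

test_that("shifting every voxel by one interval width advances labels one step", {
  curve <- toy_curve()   # linear: all intervals have equal width
  db <- build_tissue_db(curve, grid = tissue_grid(7.0, 9.0, 0.2))
  width <- db$tissues$hu_hi[2] - db$tissues$hu_lo[2]
  set.seed(8)
  # interior HU away from the first/last catch-all intervals
  hu <- array(runif(125, db$tissues$hu_lo[3], db$tissues$hu_hi[8] - 1e-9), c(5, 5, 5))
  l1 <- segment_volume(image_volume(hu), db)
  l2 <- segment_volume(image_volume(hu + width), db)
  expect_identical(l2$labels, l1$labels + 1L)
})

test_that("label histogram of a noiseless phantom equals ground-truth region sizes", {
  spec <- make_default_phantoms(spacing = c(0.5, 0.5, 0.5))$cylinders
  truth <- rasterize_phantom(spec)
  db <- build_tissue_db()
  vol <- simulate_hu(truth, icru_rho_zeff(), db$curve, sigma = 0)
  lab <- segment_volume(vol, db)
  want <- expected_labels(truth, db)
  expect_identical(as.vector(lab$labels), as.integer(want))
  h_truth <- table(as.vector(truth$labels))
  h_lab <- table(want)
  expect_equal(sum(h_lab), sum(h_truth))
})

test_that("label overrides apply only inside the mask", {
  db <- build_tissue_db()
  vol <- image_volume(array(predict_hu(db$curve, 8.0), c(4, 4, 4)))
  lab <- segment_volume(vol, db)
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, , ] <- TRUE
  out <- override_labels(lab, mask, 0)
  expect_true(all(out$labels[1:2, , ] == 0))
  expect_identical(out$labels[3:4, , ], lab$labels[3:4, , ])
  expect_error(override_labels(lab, mask, 999L), "legend")
})

test_that("Monte Carlo material export writes contiguous parseable records", {
  db <- build_tissue_db(toy_curve(), grid = c(7.6, 7.8, 8.0))
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "materials.db"); rp <- file.path(dir, "ranges.txt")
  export_mc_materials(db, mp, rp)
  back <- read_mc_materials(mp, rp)
  expect_equal(nrow(back), 3)
  # mass fractions survive 6-decimal rounding, summing to 1 within 1e-4
  w <- as.matrix(back[element_cols(back)])
  w[is.na(w)] <- 0
  expect_true(all(abs(rowSums(w) - 1) <= 1e-4))
  # densities reconstruct to 1e-4 g/cm3
  expect_equal(back$rho, db$tissues$rho, tolerance = 1e-4)
  # ranges contiguous and matching the database intervals
  expect_equal(back$hu_lo, db$tissues$hu_lo, tolerance = 1e-6)
  expect_equal(back$hu_hi[-3], back$hu_lo[-1], tolerance = 1e-12)
})
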