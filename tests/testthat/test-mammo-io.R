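test_that("DICOM reading rescales, inverts MONOCHROME1, and reads metadata", {
  set.seed(11)
  vals <- matrix(sample.int(4096, 8 * 6, replace = TRUE) - 1L, 8, 6)
  vals[1, 1] <- 0L; vals[8, 6] <- 4095L  # pin the range
  f1 <- withr::local_tempfile(fileext = ".dcm")
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(f1, vals, photometric = "MONOCHROME1")
  write_dicom_fixture(f2, vals, photometric = "MONOCHROME2")

  img1 <- read_dicom_mammogram(f1)
  # manual oracle: invert then min-max rescale
  inv <- -vals
  expected <- (inv - min(inv)) / (max(inv) - min(inv))
  expect_equal(img1$pixels, expected, tolerance = 1e-12)
  expect_true(all(img1$pixels >= 0 & img1$pixels <= 1))
  expect_equal(img1$laterality, "L")
  expect_equal(img1$view, "MLO")

  # MONOCHROME2 of the inverted array gives identical pixels
  f3 <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(f3, 4095L - vals, photometric = "MONOCHROME2")
  img3 <- read_dicom_mammogram(f3)
  expect_equal(img3$pixels, img1$pixels, tolerance = 1e-12)

  # rescale slope/intercept are honored (affine map, same normalized image)
  f4 <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(f4, vals, photometric = "MONOCHROME2",
                      slope = 2, intercept = -100)
  img2 <- read_dicom_mammogram(f2)
  expect_equal(read_dicom_mammogram(f4)$pixels, img2$pixels, tolerance = 1e-12)
})

test_that("DICOM error paths: missing pixel data, missing file", {
  vals <- matrix(0:23, 4, 6)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_dicom_fixture(f, vals, include_pixeldata = FALSE)
  expect_error(read_dicom_mammogram(f), "no pixel data")
  expect_error(read_dicom_mammogram(tempfile()), "not found")
})

test_that("mask write/read round-trips bit-exactly, 8- and 16-bit agree", {
  set.seed(3)
  m <- matrix(runif(32 * 32) > 0.5, 32, 32)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask(m, f)
  expect_identical(read_mask(f)$values, m)

  # empty mask
  f0 <- withr::local_tempfile(fileext = ".png")
  write_mask(matrix(FALSE, 5, 7), f0)
  rm0 <- read_mask(f0)
  expect_equal(mask_area(rm0), 0)

  # 16-bit TIFF from the same boolean grid gives the same mask
  f16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m * 1.0, f16, bits.per.sample = 16)
  expect_identical(read_mask(f16)$values, m)

  # RGB with unequal channels is rejected
  frgb <- withr::local_tempfile(fileext = ".png")
  arr <- array(runif(5 * 5 * 3), c(5, 5, 3))
  png::writePNG(arr, frgb)
  expect_error(read_mask(frgb), "unequal channels")
})

test_that("orientation canonicalization is an involution and infers the side", {
  ph <- generate_phantom(phantom_spec(side = "R"))
  img <- ph$image
  canon <- normalize_orientation(img)
  expect_true(canon$flipped)
  # flipping back restores the original pixel grid
  back <- canon
  back$pixels <- back$pixels[, ncol(back$pixels):1]
  expect_identical(back$pixels, img$pixels)
  # pixel multiset preserved
  expect_identical(sort(as.vector(canon$pixels)), sort(as.vector(img$pixels)))
  # idempotent on canonical input
  again <- normalize_orientation(canon)
  expect_identical(again$pixels, canon$pixels)

  # left phantom unchanged
  phL <- generate_phantom(phantom_spec(side = "L"))
  canL <- normalize_orientation(phL$image)
  expect_false(canL$flipped)
  expect_identical(canL$pixels, phL$image$pixels)

  # side inferred from border intensities when metadata is stripped
  stripped <- ph$image
  stripped$chest_wall_side <- NA_character_
  stripped$laterality <- "unknown"
  inferred <- normalize_orientation(stripped)
  expect_true(inferred$flipped)

  # ambiguous borders: warns, no flip
  flat <- mammogram(matrix(runif(50 * 50), 50, 50), image_id = "flat")
  expect_warning(res <- normalize_orientation(flat), "ambiguous")
  expect_true(res$ambiguous_orientation)
  expect_false(res$flipped)
})

test_that("constant images normalize to zero and are flagged degenerate", {
  img <- mammogram(matrix(0.7, 10, 10))
  expect_true(img$degenerate)
  expect_true(all(img$pixels == 0))
  expect_error(segment_pectoral(img), "degenerate")
})

test_that("overlay rendering accepts a phantom pectoral mask", {
  ph <- generate_phantom(phantom_spec(n_rows = 64, n_cols = 48,
                                      pectoral = list(present = TRUE, top_column = 26,
                                                      exit_row = 46, curvature = 0)))
  f <- withr::local_tempfile(fileext = ".png")
  write_overlay(ph$image, ph$truth_pectoral, f)
  arr <- png::readPNG(f)
  expect_equal(dim(arr)[3], 3)
  # some pure-red boundary pixels exist
  expect_true(any(arr[, , 1] == 1 & arr[, , 2] == 0 & arr[, , 3] == 0))
})
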