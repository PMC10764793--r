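make_cube <- function(rows = 8, cols = 9, bands = 3,
                      wl = c(446.6, 550, 632)) {
  set.seed(1)
  spectral_cube(array(runif(rows * cols * bands), c(rows, cols, bands)),
                wl)
}

test_that("cube construction enforces its invariants", {
  expect_error(spectral_cube(array(1, c(4, 4, 2)), c(400, 500)),
               "8 x 8")
  arr <- array(1, c(8, 8, 2))
  expect_error(spectral_cube(arr, c(500, 400)), "increasing")
  expect_error(spectral_cube(arr, 500), "bands")
  arr[1] <- NA
  expect_error(spectral_cube(arr, c(400, 500)), "finite")
})

test_that("ENVI round trip is lossless and interleave-invariant", {
  cube <- make_cube()
  tmp <- withr::local_tempdir()
  for (il in c("bsq", "bil", "bip")) {
    dp <- file.path(tmp, paste0("c_", il, ".raw"))
    write_envi_cube(cube, dp, interleave = il, data_type = 5)
    back <- read_envi_cube(dp)
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm)
  }
})

test_that("integer ENVI types round-trip integer data", {
  arr <- array(sample(0:255, 8 * 8 * 2, replace = TRUE), c(8, 8, 2))
  cube <- spectral_cube(arr * 1.0, c(400, 500))
  tmp <- withr::local_tempdir()
  dp <- file.path(tmp, "u8.raw")
  write_envi_cube(cube, dp, data_type = 1)
  expect_identical(read_envi_cube(dp)$data, arr * 1.0)
  dp16 <- file.path(tmp, "u16.raw")
  write_envi_cube(cube, dp16, data_type = 12)
  expect_identical(read_envi_cube(dp16)$data, arr * 1.0)
})

test_that("malformed ENVI inputs raise targeted errors", {
  cube <- make_cube()
  tmp <- withr::local_tempdir()
  dp <- file.path(tmp, "c.raw")
  write_envi_cube(cube, dp)
  hdr <- readLines(paste0(dp, ".hdr"))
  # missing wavelength list
  writeLines(hdr[!grepl("^wavelength", hdr)], file.path(tmp, "nw.hdr"))
  expect_error(read_envi_cube(dp, file.path(tmp, "nw.hdr")),
               "wavelength")
  # band count mismatch vs file size
  writeLines(sub("^bands = 3", "bands = 5", hdr),
             file.path(tmp, "nb.hdr"))
  expect_error(read_envi_cube(dp, file.path(tmp, "nb.hdr")))
  # unsupported data type
  writeLines(sub("^data type = 5", "data type = 6", hdr),
             file.path(tmp, "dt.hdr"))
  expect_error(read_envi_cube(dp, file.path(tmp, "dt.hdr")),
               "data type")
})

test_that("header keys parse case-insensitively", {
  cube <- make_cube()
  tmp <- withr::local_tempdir()
  dp <- file.path(tmp, "c.raw")
  write_envi_cube(cube, dp)
  hdr <- toupper(readLines(paste0(dp, ".hdr")))
  writeLines(hdr, file.path(tmp, "up.hdr"))
  back <- read_envi_cube(dp, file.path(tmp, "up.hdr"))
  expect_identical(back$data, cube$data)
})

test_that("band selection picks the nearest wavelength, ties low", {
  cube <- make_cube(wl = c(440, 446.6, 450))
  sel <- select_band(cube, 446.6)
  expect_equal(sel$band, 2L)
  expect_equal(sel$actual_nm, 446.6)
  cube2 <- make_cube(bands = 2, wl = c(630, 635))
  expect_equal(select_band(cube2, 632)$actual_nm, 630)
  cube3 <- make_cube(bands = 2, wl = c(400, 500))
  expect_equal(select_band(cube3, 450)$actual_nm, 400)
  expect_error(select_band(cube3, 700), "outside")
  # idempotence: re-selecting at the returned wavelength is stable
  sel2 <- select_band(cube2, 632)
  sel3 <- select_band(cube2, sel2$actual_nm)
  expect_identical(sel3$image, sel2$image)
})

test_that("mask PNG round trip preserves binary labels", {
  tmp <- withr::local_tempdir()
  z <- matrix(0L, 10, 12)
  write_mask(z, file.path(tmp, "z.png"))
  expect_identical(read_mask(file.path(tmp, "z.png")), z)
  o <- matrix(1L, 10, 12)
  write_mask(o, file.path(tmp, "o.png"))
  expect_identical(read_mask(file.path(tmp, "o.png")), o)
  set.seed(2)
  m <- matrix(rbinom(120, 1, 0.4), 10, 12)
  write_mask(m, file.path(tmp, "m.png"))
  expect_identical(read_mask(file.path(tmp, "m.png")), m)
  # mid-gray thresholds at > 127/255
  png::writePNG(matrix(c(120, 135) / 255, 2, 2), file.path(tmp, "g.png"))
  expect_identical(read_mask(file.path(tmp, "g.png")),
                   matrix(c(0L, 1L, 0L, 1L), 2, 2))
})
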