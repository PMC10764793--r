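carrier_line <- function(f, phi0, n = 256, a = 1) {
  a * cos(2 * pi * f * (0:(n - 1)) / n + phi0)
}

test_that("forward/inverse spectra are exact inverses", {
  set.seed(8)
  img <- matrix(rnorm(12 * 16), 12, 16)
  expect_equal(Re(inverse_spectrum(forward_spectrum(img))), img,
               tolerance = 1e-12)
  # delta image has a flat unit spectrum
  delta <- matrix(0, 8, 8); delta[1, 1] <- 1
  expect_equal(forward_spectrum(delta), matrix(1 + 0i, 8, 8))
  # pure cosine along columns concentrates at the +/- carrier bins
  cosimg <- matrix(rep(carrier_line(4, 0, 32), each = 8), 8, 32,
                   byrow = FALSE)
  sp <- Mod(forward_spectrum(cosimg))
  expect_equal(which(sp[1, ] > 1e-9), c(5L, 29L))  # bins +-4
})

test_that("reference deconvolution is a regularized division", {
  set.seed(9)
  img <- matrix(rnorm(64), 8, 8)
  sp <- forward_spectrum(img)
  # dividing a spectrum by itself approaches the unit spectrum
  out <- deconvolve_reference(sp, sp, epsilon = 1e-12)
  expect_equal(Mod(out)[Mod(sp) > 1e-6],
               rep(1, sum(Mod(sp) > 1e-6)), tolerance = 1e-4)
  # a delta reference (all-ones spectrum) is the identity
  expect_equal(deconvolve_reference(sp, matrix(1 + 0i, 8, 8),
                                    epsilon = 1e-15),
               sp, tolerance = 1e-9)
  # zero reference stays bounded by the regularizer
  zero <- matrix(0 + 0i, 8, 8)
  expect_true(all(Mod(deconvolve_reference(sp, zero, 1e-3)) == 0))
  expect_error(deconvolve_reference(sp, matrix(0i, 2, 2)), "shape")
})

test_that("analytic phase recovers carrier offsets to 1e-6", {
  img <- rbind(carrier_line(8, 0.7), carrier_line(8, 0.7))
  pm <- analytic_phase(img)
  expect_equal(pm$phase[1, 1], 0.7, tolerance = 1e-6)
  expect_equal(analytic_phase(rbind(carrier_line(8, 0)))$phase[1, 1], 0,
               tolerance = 1e-6)
  # full wrapped-range output, amplitude recovers the envelope
  expect_true(all(pm$phase > -pi & pm$phase <= pi))
  expect_equal(pm$amplitude[1, ], rep(1, 256), tolerance = 1e-9)
})

test_that("constant lines are flagged degenerate with zero phase", {
  img <- rbind(carrier_line(8, 0.3), rep(2, 256))
  expect_warning(pm <- analytic_phase(img), "no fluctuation")
  expect_equal(pm$phase[2, ], rep(0, 256))
  expect_equal(pm$amplitude[2, ], rep(0, 256))
  expect_identical(pm$flat_lines, c(FALSE, TRUE))
})

test_that("translation shifts recovered phase by 2*pi*f*dx/N", {
  n <- 256; f <- 8; dx <- 5
  base <- rbind(carrier_line(f, 0, n))
  shifted <- rbind(carrier_line(f, 2 * pi * f * dx / n, n))
  dp <- wrap_phase(analytic_phase(shifted)$phase -
                     analytic_phase(base)$phase)
  expect_equal(dp[1, 20:230], rep(wrap_phase(2 * pi * f * dx / n), 211),
               tolerance = 1e-6)
})

test_that("synchronous demodulation matches the analytic route on pure carriers and recovers plateaus exactly", {
  img <- rbind(carrier_line(8, 1.2), carrier_line(8, 1.2))
  sm <- synchronous_phase(img)
  am <- analytic_phase(img)
  expect_equal(attr(sm, "carrier_cycles"), 8L)
  # away from the boxcar's edge-reflection zone the two routes agree
  expect_equal(sm$phase[1, 17:240], am$phase[1, 17:240],
               tolerance = 1e-9)
  expect_equal(sm$amplitude[1, 17:240], rep(1, 224), tolerance = 1e-9)
  # piecewise-constant phase step: interior exact away from the step,
  # where the analytic route still carries 1/distance ringing
  n <- 160; f <- 8
  phi <- rep(0, n); phi[60:100] <- 1.3
  line <- cos(2 * pi * f * (0:(n - 1)) / n + phi)
  sp <- synchronous_phase(rbind(line), carrier_cycles = f)
  rec <- wrap_phase(sp$phase[1, ] - 2 * pi * f * (0:(n - 1)) / n)
  expect_equal(rec[75:85], rep(1.3, 11), tolerance = 1e-12)
  expect_equal(rec[20:45], rep(0, 26), tolerance = 1e-12)
  expect_error(synchronous_phase(matrix(1, 4, 16)), "carrier")
})

test_that("relative phase and shift maps follow wrap arithmetic", {
  a <- matrix(3.0, 4, 4); b <- matrix(-3.0, 4, 4)
  rel <- phase_relative_to_reference(a, b)
  expect_equal(rel$phase, matrix(6 - 2 * pi, 4, 4), tolerance = 1e-12)
  expect_equal(phase_relative_to_reference(a, a)$phase,
               matrix(0, 4, 4))
  expect_equal(phase_relative_to_reference(a, matrix(0, 4, 4))$phase, a)

  sm <- phase_shift_map(a, b)
  expect_equal(sm$dphi, matrix(abs(6 - 2 * pi), 4, 4), tolerance = 1e-12)
  expect_equal(phase_shift_map(a, a)$dphi, matrix(0, 4, 4))
  expect_equal(phase_shift_map(matrix(pi / 2, 3, 3),
                               matrix(-pi / 2, 3, 3))$dphi,
               matrix(pi, 3, 3))
  expect_error(phase_shift_map(a, matrix(0, 2, 2)), "shape")
})

test_that("line profiles index rows 0-based from the image top", {
  m <- matrix(seq_len(12), 3, 4, byrow = TRUE)
  expect_equal(line_profile(m, 0), c(1, 2, 3, 4))
  expect_equal(line_profile(m, 2), c(9, 10, 11, 12))
  expect_length(line_profile(m, 1), ncol(m))
  expect_error(line_profile(m, 3), "out of range")
})

test_that("phase stacks order bands ascending and track tumor depth visibility", {
  sc <- small_scene(noise_sigma = 0,
                    tumor_regions = list(c(36, 40, 10, 12, 40)))
  po <- render_phantom(sc)
  st <- suppressWarnings(
    phase_stack(po$cube, strip_rows(sc), c(632, 446.6)))
  expect_equal(dim(st$phase)[3], 2L)
  expect_equal(st$wavelengths_nm, c(446.6, 632))
  one <- suppressWarnings(phase_stack(po$cube, strip_rows(sc), 632))
  expect_equal(dim(one$phase)[3], 1L)
  expect_equal(one$phase[, , 1], st$phase[, , 2])
  # deep tumor: visible in the red slice, buried for blue
  dev_for <- function(slice) {
    normal <- po$truth == 0; normal[strip_rows(sc), ] <- FALSE
    ref_col <- vapply(seq_len(ncol(slice)), function(j)
      stats::median(slice[normal[, j], j]), 0)
    dev <- abs(wrap_phase(sweep(slice, 2, ref_col)))
    mean(dev[po$truth == 1])
  }
  expect_lt(dev_for(st$phase[, , 1]), 0.1 * dev_for(st$phase[, , 2]))
  expect_error(phase_stack(po$cube, strip_rows(sc), numeric(0)),
               "non-empty")
})
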