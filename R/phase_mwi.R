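#' Construct a per-band phase map
#'
#' Holds the wrapped per-pixel phase (radians, in `(-pi, pi]`) of one
#' spectral band relative to the white reference, together with the
#' demodulation amplitude envelope and, optionally, per-line degeneracy
#' flags for lines with no measurable fluctuation.
#'
#' @param phase numeric matrix of wrapped phase values.
#' @param amplitude non-negative matrix, same shape.
#' @param wavelength_nm band wavelength (or `NA`).
#' @param flat_lines optional logical vector marking degenerate lines.
#' @return an object of class `phase_map`.
#' @export
phase_map <- function(phase, amplitude, wavelength_nm = NA_real_,
                      flat_lines = NULL) {
  stopifnot(is.matrix(phase), identical(dim(phase), dim(amplitude)))
  dimnames(phase) <- NULL
  dimnames(amplitude) <- NULL
  if (any(phase <= -pi | phase > pi))
    stop("phase values must lie in (-pi, pi]")
  if (any(amplitude < 0)) stop("amplitude must be >= 0")
  structure(list(phase = phase, amplitude = amplitude,
                 wavelength_nm = wavelength_nm,
                 flat_lines = flat_lines),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d x %d px at %.1f nm; phase in (-pi, pi]\n",
              nrow(x$phase), ncol(x$phase), x$wavelength_nm))
  invisible(x)
}

#' 2-D forward Fourier spectrum of an image
#'
#' Standard unnormalized 2-D DFT with the zero-frequency term at
#' element `[1, 1]`; inverted exactly by [inverse_spectrum()].
#'
#' @param image real-valued matrix.
#' @return complex matrix of the same shape.
#' @export
forward_spectrum <- function(image) {
  stopifnot(is.matrix(image))
  stats::fft(image)
}

#' Inverse of [forward_spectrum()]
#'
#' @param spectrum complex matrix.
#' @return complex matrix; take `Re()` for real inputs.
#' @export
inverse_spectrum <- function(spectrum) {
  stats::fft(spectrum, inverse = TRUE) / length(spectrum)
}

#' Regularized deconvolution by a reference spectrum
#'
#' Wiener-style division `out = S * Conj(R) / (|R|^2 + epsilon)`: where
#' the reference has power, this divides out its transfer function;
#' where `|R| ~ 0` the output stays bounded by the regularizer.
#'
#' @param spectrum,reference_spectrum complex matrices, same shape.
#' @param epsilon positive regularizer.
#' @return complex matrix.
#' @export
deconvolve_reference <- function(spectrum, reference_spectrum,
                                 epsilon = 1e-6) {
  if (!identical(dim(spectrum), dim(reference_spectrum)))
    stop("spectra must have the same shape")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  spectrum * Conj(reference_spectrum) /
    (Mod(reference_spectrum)^2 + epsilon)
}

#' Analytic-signal phase extraction along the carrier axis
#'
#' Demodulates the spatial carrier fringe line by line: each line is
#' mean-centered, its analytic signal is formed by the one-dimensional
#' Fourier transform (strictly negative frequency bins zeroed, strictly
#' positive bins doubled; DC and the Nyquist bin, when present, kept),
#' and inverted; the local phase is the argument of the analytic
#' signal, the envelope its modulus. Lines with no measurable
#' fluctuation get phase 0, amplitude 0 and are flagged (with one
#' warning per call).
#'
#' @param image real matrix carrying a dominant fluctuation along
#'   `carrier_axis`.
#' @param carrier_axis `"cols"` (each row is a line; default) or
#'   `"rows"`.
#' @param wavelength_nm carried through to the result.
#' @return a [phase_map()] with `flat_lines` flags.
#' @export
analytic_phase <- function(image, carrier_axis = c("cols", "rows"),
                           wavelength_nm = NA_real_) {
  carrier_axis <- match.arg(carrier_axis)
  stopifnot(is.matrix(image), all(is.finite(image)))
  x <- if (carrier_axis == "cols") t(image) else image
  # lines are now the columns of x
  npts <- nrow(x)
  centered <- sweep(x, 2, colMeans(x))
  scale_ref <- pmax(1, apply(abs(x), 2, max))
  flat <- apply(abs(centered), 2, max) <= 1e-12 * scale_ref
  w <- numeric(npts)
  w[1] <- 1
  if (npts %% 2L == 0L) {
    w[npts / 2 + 1] <- 1
    if (npts > 2) w[2:(npts / 2)] <- 2
  } else if (npts > 1) {
    w[2:((npts + 1) / 2)] <- 2
  }
  Z <- stats::mvfft(centered) * w
  z <- stats::mvfft(Z, inverse = TRUE) / npts
  ph <- Arg(z)
  am <- Mod(z)
  if (any(flat)) {
    warning(sprintf("%d line(s) have no fluctuation; phase set to 0",
                    sum(flat)))
    ph[, flat] <- 0
    am[, flat] <- 0
  }
  # Arg() returns values in [-pi, pi]; fold -pi onto +pi
  ph[ph <= -pi] <- pi
  if (carrier_axis == "cols") {
    ph <- t(ph); am <- t(am)
  }
  phat <- phase_map(ph, am, wavelength_nm = wavelength_nm,
                    flat_lines = unname(flat))
  phat
}

#' Phase relative to a reference phase map
#'
#' Elementwise wrapped difference `wrap(sample - reference)` in
#' `(-pi, pi]`.
#'
#' @param sample_phase,reference_phase [phase_map()] objects (or bare
#'   matrices) of the same shape.
#' @return a [phase_map()]; the amplitude is taken from the sample.
#' @export
phase_relative_to_reference <- function(sample_phase, reference_phase) {
  sp <- if (inherits(sample_phase, "phase_map")) sample_phase
        else phase_map(wrap_phase(sample_phase),
                       matrix(1, nrow(sample_phase), ncol(sample_phase)))
  rp <- if (inherits(reference_phase, "phase_map")) reference_phase$phase
        else reference_phase
  if (!identical(dim(sp$phase), dim(rp)))
    stop("sample and reference phase maps must have the same shape")
  phase_map(wrap_phase(sp$phase - rp), sp$amplitude,
            wavelength_nm = sp$wavelength_nm, flat_lines = sp$flat_lines)
}

#' Absolute inter-wavelength phase-shift map
#'
#' The classification feature: `dphi = |wrap(phase1 - phase2)|`, in
#' `[0, pi]`, between two bands (conventionally blue and red).
#'
#' @param phase1,phase2 [phase_map()] objects (or matrices), same shape.
#' @return an object of class `phase_shift_map` with fields `dphi`
#'   (matrix in `[0, pi]`) and `pair` (the two wavelengths, nm).
#' @export
phase_shift_map <- function(phase1, phase2) {
  p1 <- if (inherits(phase1, "phase_map")) phase1$phase else phase1
  p2 <- if (inherits(phase2, "phase_map")) phase2$phase else phase2
  if (!identical(dim(p1), dim(p2)))
    stop("phase maps must have the same shape")
  w1 <- if (inherits(phase1, "phase_map")) phase1$wavelength_nm else NA_real_
  w2 <- if (inherits(phase2, "phase_map")) phase2$wavelength_nm else NA_real_
  dphi <- abs(wrap_phase(p1 - p2))
  stopifnot(all(dphi >= 0 & dphi <= pi))
  structure(list(dphi = dphi, pair = c(w1, w2)),
            class = "phase_shift_map")
}

#' @export
print.phase_shift_map <- function(x, ...) {
  cat(sprintf(
    "<phase_shift_map> %d x %d px, pair %.1f / %.1f nm, dphi in [0, pi]\n",
    nrow(x$dphi), ncol(x$dphi), x$pair[1], x$pair[2]))
  invisible(x)
}

#' Horizontal line profile of a map
#'
#' Extracts one image row as a 1-D signal for plotting, the way phase
#' results are conventionally inspected at a fixed horizontal line.
#' `row_index` is 0-based to match image coordinates (row 0 = top).
#'
#' @param map a [phase_map()], [phase_shift_map()] or plain matrix.
#' @param row_index 0-based row index.
#' @return numeric vector of length `ncol`.
#' @export
line_profile <- function(map, row_index) {
  m <- if (inherits(map, "phase_map")) map$phase
       else if (inherits(map, "phase_shift_map")) map$dphi
       else map
  if (row_index < 0 || row_index >= nrow(m))
    stop("`row_index` out of range (0-based)")
  as.vector(m[row_index + 1L, ])
}

#' Dominant fluctuation frequency of a set of lines
#'
#' The carrier estimate used by [synchronous_phase()]: the positive
#' DFT bin with the largest magnitude in the spectrum of the mean
#' line (cycles per line length). Returns 0 when the mean line has no
#' measurable fluctuation.
#'
#' @param lines_matrix matrix with one line per row.
#' @return integer bin index (cycles across the line), or 0.
#' @export
dominant_frequency <- function(lines_matrix) {
  mean_line <- colMeans(lines_matrix)
  centered <- mean_line - mean(mean_line)
  if (max(abs(centered)) <= 1e-12 * max(1, max(abs(mean_line)))) return(0L)
  sp <- Mod(stats::fft(centered))
  npos <- floor((length(centered) - 1) / 2)
  which.max(sp[2:(1 + npos)])
}

# centered boxcar mean with symmetric reflective padding (cumsum-based);
# for even W the window extends half left, W - half - 1 right
.boxcar_reflect <- function(v, W) {
  n <- length(v)
  half <- W %/% 2
  rpad <- W - half - 1L
  right <- if (rpad > 0) rev(v[(n - rpad + 1):n]) else numeric(0)
  vp <- c(rev(v[seq_len(half)]), v, right)
  cs <- cumsum(c(0, vp))
  (cs[(W + 1):(W + n)] - cs[seq_len(n)]) / W
}

#' Carrier-locked synchronous phase demodulation
#'
#' Quadrature demodulation at the known carrier frequency: each line is
#' multiplied by `exp(-i * theta_c(x))` with
#' `theta_c = 2*pi*f*x/N`, then low-pass filtered with a boxcar of one
#' carrier period, which exactly nulls the baseband and double-frequency
#' demodulation products when the period divides the line length. The
#' local phase is `wrap(arg + theta_c)`, directly comparable to
#' [analytic_phase()] output. Unlike the analytic-signal route, whose
#' edge response decays only as 1/distance from a phase discontinuity,
#' the boxcar has finite support: a phase step contaminates at most half
#' a window on either side, so plateau interiors are recovered to
#' machine precision.
#'
#' @param image real matrix with the carrier along `carrier_axis`.
#' @param carrier_cycles carrier frequency in cycles per line; `NULL`
#'   (default) estimates it with [dominant_frequency()].
#' @param window low-pass boxcar width in pixels; default one carrier
#'   period, `round(N / f)`.
#' @param carrier_axis `"cols"` (default) or `"rows"`.
#' @param wavelength_nm carried through to the result.
#' @return a [phase_map()] with `flat_lines` flags; the estimated
#'   carrier is attached as attribute `carrier_cycles`.
#' @export
synchronous_phase <- function(image, carrier_cycles = NULL, window = NULL,
                              carrier_axis = c("cols", "rows"),
                              wavelength_nm = NA_real_) {
  carrier_axis <- match.arg(carrier_axis)
  stopifnot(is.matrix(image), all(is.finite(image)))
  lines <- if (carrier_axis == "cols") image else t(image)
  npts <- ncol(lines)
  if (is.null(carrier_cycles)) carrier_cycles <- dominant_frequency(lines)
  if (carrier_cycles < 1)
    stop("no carrier fluctuation found; supply `carrier_cycles`")
  if (is.null(window)) window <- max(2L, round(npts / carrier_cycles))
  theta_c <- 2 * pi * carrier_cycles * (0:(npts - 1)) / npts
  rot <- exp(-1i * theta_c)
  centered <- lines - rowMeans(lines)
  flat <- apply(abs(centered), 1, max) <=
    1e-12 * pmax(1, apply(abs(lines), 1, max))
  ph <- matrix(0, nrow(lines), npts)
  am <- matrix(0, nrow(lines), npts)
  for (r in seq_len(nrow(lines))) {
    if (flat[r]) next
    z <- lines[r, ] * rot
    zs <- complex(real = .boxcar_reflect(Re(z), window),
                  imaginary = .boxcar_reflect(Im(z), window))
    ph[r, ] <- wrap_phase(Arg(zs) + theta_c)
    am[r, ] <- 2 * Mod(zs)
  }
  if (any(flat))
    warning(sprintf("%d line(s) have no fluctuation; phase set to 0",
                    sum(flat)))
  ph[ph <= -pi] <- pi
  if (carrier_axis == "rows") {
    ph <- t(ph); am <- t(am)
  }
  out <- phase_map(ph, am, wavelength_nm = wavelength_nm,
                   flat_lines = unname(flat))
  attr(out, "carrier_cycles") <- carrier_cycles
  out
}

#' Per-band phase stack referenced to the white reference
#'
#' Extracts a phase map for every requested band (after white-reference
#' normalization and mean filtering per `config`), each referenced to
#' the phase of the white-reference strip's mean line, and stacks them
#' in ascending wavelength order. With wavelength as a depth proxy the
#' stack is a 3-D phase-resolved view of the scene.
#'
#' @param cube a [spectral_cube()].
#' @param reference_rows 1-based row indices of the white-reference
#'   strip within the cube.
#' @param band_list wavelengths (nm) to include; must be non-empty.
#' @param config a [preprocess_config()].
#' @return list with `phase` (rows x cols x n_bands array),
#'   `wavelengths_nm`, and `maps` (list of [phase_map()]).
#' @export
phase_stack <- function(cube, reference_rows, band_list,
                        config = preprocess_config()) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (length(band_list) == 0) stop("`band_list` must be non-empty")
  band_list <- sort(band_list)
  maps <- lapply(band_list, function(wl) {
    extract_band_phase(cube, wl, reference_rows, config = config)
  })
  arr <- array(unlist(lapply(maps, function(m) m$phase)),
               dim = c(dim(cube$data)[1:2], length(maps)))
  list(phase = arr,
       wavelengths_nm = vapply(maps, function(m) m$wavelength_nm, 0),
       maps = maps)
}

#' Extract the referenced phase map of one band
#'
#' The single-band workhorse used by the pipeline: selects the band
#' nearest `target_nm`, preprocesses it (white normalization against
#' the per-column mean of the reference-strip rows, then the remaining
#' configured stages), demodulates the carrier with [analytic_phase()],
#' and references the result to the phase of the white strip's mean
#' line (zero for a flat reference).
#'
#' @param cube a [spectral_cube()].
#' @param target_nm requested wavelength (nm).
#' @param reference_rows 1-based rows of the white-reference strip.
#' @param reference_cube optional separately acquired reference cube
#'   (used when `config$reference_strategy == "reference_cube"`).
#' @param config a [preprocess_config()].
#' @param mode `"synchronous"` (carrier-locked demodulation, default)
#'   or `"analytic"` (analytic-signal demodulation).
#' @return a [phase_map()] at the band's actual wavelength.
#' @export
extract_band_phase <- function(cube, target_nm, reference_rows,
                               reference_cube = NULL,
                               config = preprocess_config(),
                               mode = c("synchronous", "analytic")) {
  mode <- match.arg(mode)
  sel <- select_band(cube, target_nm)
  img <- sel$image
  ref_img <- if (config$reference_strategy == "reference_cube" &&
                 !is.null(reference_cube)) {
    select_band(reference_cube, target_nm)$image
  } else {
    strip <- img[reference_rows, , drop = FALSE]
    matrix(colMeans(strip), nrow(img), ncol(img), byrow = TRUE)
  }
  proc <- preprocess_image(img, ref_img, config)
  pm <- if (mode == "synchronous") {
    synchronous_phase(proc, wavelength_nm = sel$actual_nm)
  } else {
    analytic_phase(proc, wavelength_nm = sel$actual_nm)
  }
  # reference anchor: phase of the strip's mean line (0 if flat)
  strip_proc <- proc[reference_rows, , drop = FALSE]
  ref_line <- matrix(colMeans(strip_proc), nrow = 1)
  ref_pm <- suppressWarnings(analytic_phase(ref_line))
  ref_phase <- matrix(ref_pm$phase[1, ], nrow(proc), ncol(proc),
                      byrow = TRUE)
  phase_relative_to_reference(pm, ref_phase)
}
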