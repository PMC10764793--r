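#' Parametric phantom scene
#'
#' Describes a synthetic hyperspectral scene: a flat white-paper
#' reference strip across the top rows, tissue below, and elliptical
#' tumor inclusions whose refractive-index contrast against the normal
#' medium is encoded as a phase offset riding on a spatial carrier
#' fringe along the columns. Longer wavelengths probe deeper: each
#' band's penetration depth scales linearly with wavelength, so a tumor
#' buried below the blue penetration limit perturbs the red band but
#' not the blue one — the depth/wavelength contrast the two-band
#' phase-shift feature exploits.
#'
#' Tumor rows are given 0-based, row 0 at the image top.
#'
#' @param rows,cols image size in pixels (>= 8 each).
#' @param wavelengths_nm band centers; default 128 bands, 380-1015 nm
#'   in 5 nm steps.
#' @param reference_strip 0-based inclusive row range `c(first, last)`
#'   of the white strip.
#' @param normal_medium,tumor_medium [optical_medium()] descriptions of
#'   the two tissue classes.
#' @param tumor_regions list of tumors, each
#'   `c(center_row, center_col, semi_axis_r, semi_axis_c, depth_um)`
#'   (centers 0-based; depth in micrometres).
#' @param carrier_cycles carrier frequency in cycles across the image
#'   width; must stay below `cols / 4` (Nyquist margin).
#' @param noise_sigma additive Gaussian noise SD as a fraction of full
#'   scale (default 0.02).
#' @param penetration_632_um penetration depth at 632 nm (um); the
#'   per-band limit is `penetration_632_um * lambda / 632`.
#' @param penetration_rolloff_um e-folding length (um) of the phase
#'   visibility once a tumor lies deeper than a band's penetration
#'   limit.
#' @param seed integer RNG seed; all stochastic draws flow from it.
#' @return an object of class `phantom_scene`.
#' @export
phantom_scene <- function(rows = 128L, cols = 160L,
                          wavelengths_nm = seq(380, by = 5,
                                               length.out = 128),
                          reference_strip = c(0L, 15L),
                          normal_medium = optical_medium(
                            n_g = 1.36, n_sc = 1.45, c_sc = 0.2,
                            r_um = 0.5, Vs_per_um3 = 0.1),
                          tumor_medium = optical_medium(
                            n_g = 1.36, n_sc = 1.45, c_sc = 0.5,
                            r_um = 0.5, Vs_per_um3 = 0.1),
                          tumor_regions = list(
                            c(60, 60, 18, 22, 7),
                            c(95, 110, 14, 16, 10)),
                          carrier_cycles = 8,
                          noise_sigma = 0.02,
                          penetration_632_um = 50,
                          penetration_rolloff_um = 2,
                          seed = 1L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 8L || cols < 8L) stop("scene must be at least 8 x 8")
  if (carrier_cycles <= 0 || carrier_cycles >= cols / 4)
    stop("`carrier_cycles` must satisfy 0 < f < cols/4 (Nyquist margin)")
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (reference_strip[1] < 0 || reference_strip[2] >= rows ||
      reference_strip[1] > reference_strip[2])
    stop("invalid `reference_strip` row range")
  tissue_top <- reference_strip[2] + 1L
  for (tr in tumor_regions) {
    if (length(tr) != 5L) stop("each tumor is (row, col, ar, ac, depth)")
    if (tr[1] - tr[3] <= tissue_top || tr[1] + tr[3] >= rows ||
        tr[2] - tr[4] < 0 || tr[2] + tr[4] >= cols)
      stop("tumor ellipse extends outside the tissue region")
    if (tr[5] <= 0) stop("tumor depth must be positive")
  }
  structure(list(rows = rows, cols = cols,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 reference_strip = as.integer(reference_strip),
                 normal_medium = normal_medium,
                 tumor_medium = tumor_medium,
                 tumor_regions = tumor_regions,
                 carrier_cycles = carrier_cycles,
                 noise_sigma = noise_sigma,
                 penetration_632_um = penetration_632_um,
                 penetration_rolloff_um = penetration_rolloff_um,
                 seed = as.integer(seed)),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %d x %d px, %d bands, %d tumor(s), noise %.3f, seed %d\n",
    x$rows, x$cols, length(x$wavelengths_nm), length(x$tumor_regions),
    x$noise_sigma, x$seed))
  invisible(x)
}

# run fn() with a private RNG stream seeded by `seed`
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Render a phantom scene into a cube with ground truth
#'
#' For every band of wavelength lambda the reference strip is flat
#' intensity 1; tissue pixels are
#' `R(lambda) * (1 + 0.5 * cos(2*pi*f*col/cols + phi))` plus additive
#' Gaussian noise. The band reflectance
#' `R(lambda) = exp(-k * mu_sc(lambda) * 632/lambda)` follows the
#' normal medium's scattering coefficient, with `k` fixed so that
#' `R(632 nm) = 0.6`; the `632/lambda` factor makes short wavelengths
#' attenuate faster. Inside a tumor of depth `d` the offset is
#' `phi = v * wrap(2*pi * 2*dn*d / lambda)` — a reflection-geometry
#' (round-trip) optical path with index contrast
#' `dn = n_m(tumor) - n_m(normal)` — scaled by the visibility
#' `v = exp(-max(0, d - Lp(lambda)) / rolloff)`,
#' `Lp(lambda) = penetration_632_um * lambda/632`, which drives the
#' observed offset to zero once the tumor lies below the band's
#' penetration depth. Deterministic given the scene seed.
#'
#' @param scene a [phantom_scene()].
#' @return list of class `phantom_output`: `cube` ([spectral_cube()]),
#'   `truth` (0/1 matrix), `depth_map` (um, 0 outside tumors),
#'   `phase_truth` (rows x cols x bands injected offsets, radians), and
#'   `scene`.
#' @export
render_phantom <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  rows <- scene$rows; cols <- scene$cols
  wl_um <- scene$wavelengths_nm / 1000
  nb <- length(wl_um)

  depth_map <- matrix(0, rows, cols)
  rr <- matrix(0:(rows - 1), rows, cols)
  cc <- matrix(0:(cols - 1), rows, cols, byrow = TRUE)
  for (tr in scene$tumor_regions) {
    inside <- ((rr - tr[1]) / tr[3])^2 + ((cc - tr[2]) / tr[4])^2 <= 1
    depth_map[inside] <- tr[5]
  }
  truth <- (depth_map > 0) * 1L

  dn <- median_refractive_index(scene$tumor_medium) -
        median_refractive_index(scene$normal_medium)
  mu <- vapply(wl_um, function(l)
    scattering_coefficient(scene$normal_medium, l), 0)
  mu_632 <- scattering_coefficient(scene$normal_medium, 0.632)
  k <- -log(0.6) / mu_632
  refl <- exp(-k * mu * (0.632 / wl_um))

  strip_rows <- (scene$reference_strip[1]:scene$reference_strip[2]) + 1L
  tissue <- matrix(TRUE, rows, cols)
  tissue[strip_rows, ] <- FALSE
  carrier <- 2 * pi * scene$carrier_cycles * cc / cols

  cube_data <- array(0, dim = c(rows, cols, nb))
  phase_truth <- array(0, dim = c(rows, cols, nb))
  .with_seed(scene$seed, function() {
    for (b in seq_len(nb)) {
      lp <- scene$penetration_632_um * wl_um[b] / 0.632
      vis <- exp(-pmax(0, depth_map - lp) / scene$penetration_rolloff_um)
      phi <- matrix(0, rows, cols)
      in_tumor <- depth_map > 0
      if (any(in_tumor)) {
        phi[in_tumor] <- vis[in_tumor] *
          phase_from_opd(2 * dn * depth_map[in_tumor], wl_um[b])
      }
      phi[!tissue] <- 0
      band <- matrix(1, rows, cols)
      band[tissue] <- refl[b] *
        (1 + 0.5 * cos(carrier[tissue] + phi[tissue]))
      if (scene$noise_sigma > 0)
        band <- band + matrix(stats::rnorm(rows * cols, 0,
                                           scene$noise_sigma),
                              rows, cols)
      cube_data[, , b] <<- band
      phase_truth[, , b] <<- phi
    }
  })
  cube_data <- pmax(cube_data, 0)
  out <- list(
    cube = spectral_cube(cube_data, scene$wavelengths_nm,
                         meta = list(source = "mwiphase phantom",
                                     seed = scene$seed)),
    truth = truth, depth_map = depth_map, phase_truth = phase_truth,
    scene = scene)
  class(out) <- "phantom_output"
  out
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf(
    "<phantom_output> cube %s, %d tumor px (%.1f%% of frame)\n",
    paste(dim(x$cube$data), collapse = " x "), sum(x$truth),
    100 * mean(x$truth)))
  invisible(x)
}

#' Generate a set of phantom acquisitions
#'
#' Emulates repeated specimen acquisitions: `n_samples` renders of the
#' template scene with tumor centers/sizes jittered and fresh noise,
#' all driven by one master seed (reproducible).
#'
#' @param scene_template a [phantom_scene()].
#' @param n_samples number of scenes (>= 1).
#' @param seed master seed for the jitter and per-sample noise seeds.
#' @param jitter_px SD of the tumor center jitter in pixels (default 3).
#' @return list of `phantom_output` objects.
#' @export
make_training_set <- function(scene_template, n_samples, seed = 1L,
                              jitter_px = 3) {
  stopifnot(inherits(scene_template, "phantom_scene"), n_samples >= 1)
  if (n_samples == 1 && jitter_px == 0)
    return(list(render_phantom(scene_template)))
  .with_seed(seed, function() {
    lapply(seq_len(n_samples), function(i) {
      sc <- scene_template
      sc$tumor_regions <- lapply(sc$tumor_regions, function(tr) {
        tr[1:2] <- round(tr[1:2] + stats::rnorm(2, 0, jitter_px))
        # keep the jittered ellipse inside the tissue region
        tr[1] <- min(max(tr[1], sc$reference_strip[2] + 1 + tr[3] + 1),
                     sc$rows - tr[3] - 2)
        tr[2] <- min(max(tr[2], tr[4]), sc$cols - tr[4] - 2)
        tr
      })
      sc$seed <- sample.int(.Machine$integer.max, 1)
      render_phantom(sc)
    })
  })
}
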