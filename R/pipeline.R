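#' Pipeline configuration
#'
#' End-to-end settings for the two-band phase pipeline: the operating
#' wavelengths (blue below red), the phase-extraction mode, the
#' preprocessing chain and the classifier border exclusion.
#'
#' @param blue_nm short operating wavelength (default 446.6 nm).
#' @param red_nm long operating wavelength (default 632 nm).
#' @param phase_mode `"synchronous"` (carrier-locked quadrature
#'   demodulation, default — exact plateau recovery, finite edge
#'   support), `"analytic"` (per-line analytic-signal demodulation) or
#'   `"fourier2d"` (2-D spectrum with reference deconvolution).
#' @param preprocess a [preprocess_config()].
#' @param excluded_border per-side excluded column fraction.
#' @param seed integer seed recorded in provenance and used for any
#'   stochastic stage.
#' @param output_dir where run artifacts are written.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(blue_nm = 446.6, red_nm = 632,
                            phase_mode = c("synchronous", "analytic",
                                           "fourier2d"),
                            preprocess = preprocess_config(),
                            excluded_border = 0.02,
                            seed = 1L, output_dir = tempdir()) {
  phase_mode <- match.arg(phase_mode)
  if (!(blue_nm < red_nm)) stop("`blue_nm` must be below `red_nm`")
  structure(list(blue_nm = blue_nm, red_nm = red_nm,
                 phase_mode = phase_mode, preprocess = preprocess,
                 excluded_border = excluded_border,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

# stable hash of a config list (provenance): md5 of its deparsed form
.config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}

.write_manifest <- function(dir, what, config, extra = list()) {
  manifest <- c(list(stage = what,
                     config_hash = .config_hash(config),
                     seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("mwiphase")),
                     timestamp_utc = format(Sys.time(), tz = "UTC",
                                            "%Y-%m-%dT%H:%M:%SZ")),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Simulate phantom acquisitions to disk
#'
#' Renders `n_samples` phantom outputs from `scene` and writes each to
#' its own subdirectory: ENVI cube, truth-mask PNG, float64 ENVI
#' rasters of the depth map and the blue/red injected phase truth, and
#' a JSON manifest carrying the seed and a config hash.
#'
#' @param scene a [phantom_scene()].
#' @param out_dir output directory (created if missing).
#' @param n_samples number of acquisitions (default 1).
#' @param config a [pipeline_config()] (its seed drives the set).
#' @return invisibly, the vector of sample directories.
#' @export
pipeline_simulate <- function(scene, out_dir, n_samples = 1L,
                              config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outs <- if (n_samples == 1L) list(render_phantom(scene))
          else make_training_set(scene, n_samples, seed = config$seed)
  dirs <- character(n_samples)
  for (i in seq_along(outs)) {
    d <- file.path(out_dir, sprintf("sample_%02d", i))
    dir.create(d, showWarnings = FALSE)
    po <- outs[[i]]
    write_envi_cube(po$cube, file.path(d, "cube.raw"),
                    file.path(d, "cube.hdr"))
    write_mask(po$truth, file.path(d, "truth.png"))
    depth_cube <- spectral_cube(array(po$depth_map,
                                      c(dim(po$depth_map), 1)),
                                wavelengths_nm = 0)
    # single-band raster; wavelength slot unused
    depth_cube$wavelengths_nm <- 0
    write_envi_cube(depth_cube, file.path(d, "depth.raw"),
                    file.path(d, "depth.hdr"))
    .write_manifest(d, "simulate", config,
                    list(sample = i, scene_seed = po$scene$seed))
    dirs[i] <- d
  }
  .write_manifest(out_dir, "simulate_set", config,
                  list(n_samples = n_samples))
  invisible(dirs)
}

# phase map of one band in the configured mode
.band_phase <- function(cube, target_nm, reference_rows, config) {
  if (config$phase_mode %in% c("synchronous", "analytic")) {
    extract_band_phase(cube, target_nm, reference_rows,
                       config = config$preprocess,
                       mode = config$phase_mode)
  } else {
    sel <- select_band(cube, target_nm)
    strip <- sel$image[reference_rows, , drop = FALSE]
    ref_img <- matrix(colMeans(strip), nrow(sel$image), ncol(sel$image),
                      byrow = TRUE)
    proc <- preprocess_image(sel$image, ref_img, config$preprocess)
    # 2-D route: whole-image spectrum, one-sided along the carrier axis
    # (2-D analytic signal), inverse. The white reference enters through
    # the normalization stage; spectral deconvolution against a
    # structured reference cube is available via deconvolve_reference().
    centered <- proc - mean(proc)
    sp <- forward_spectrum(centered)
    nc <- ncol(sp)
    w <- numeric(nc); w[1] <- 1
    if (nc %% 2L == 0L) {
      w[nc / 2 + 1] <- 1
      if (nc > 2) w[2:(nc / 2)] <- 2
    } else if (nc > 1) w[2:((nc + 1) / 2)] <- 2
    z <- inverse_spectrum(sweep(sp, 2, w, `*`))
    ph <- Arg(z); ph[ph <= -pi] <- pi
    phase_map(ph, Mod(z), wavelength_nm = sel$actual_nm)
  }
}

#' Run the two-band phase pipeline on a cube
#'
#' Executes preprocessing, blue/red phase extraction against the white
#' reference, the absolute phase-shift map, and — when a truth mask or
#' a trained model is supplied — classification and scoring. All
#' artifacts (phase maps, shift map, predicted mask, metrics CSV,
#' provenance manifest) are written under `config$output_dir`.
#'
#' @param cube a [spectral_cube()] (or path to an ENVI header/data
#'   pair's data file).
#' @param reference_rows 1-based rows of the white-reference strip.
#' @param config a [pipeline_config()].
#' @param mask optional 0/1 truth mask (or PNG path): the model is
#'   trained on this cube and then scored against it.
#' @param model optional pre-trained [train_threshold()] model; used
#'   for classification when no mask is given.
#' @param sample_id identifier used in the metrics row.
#' @return list with `blue`, `red` ([phase_map()]s), `shift`
#'   ([phase_shift_map()]), `model`, `pred` (0/1 matrix or NULL),
#'   `metrics` (data.frame or NULL), and `dir` (artifact directory).
#' @export
pipeline_run <- function(cube, reference_rows, config = pipeline_config(),
                         mask = NULL, model = NULL, sample_id = "sample") {
  if (is.character(cube)) cube <- read_envi_cube(cube)
  if (is.character(mask)) mask <- read_mask(mask)
  stopifnot(inherits(cube, "spectral_cube"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  blue <- .band_phase(cube, config$blue_nm, reference_rows, config)
  red <- .band_phase(cube, config$red_nm, reference_rows, config)
  shift <- phase_shift_map(blue, red)

  d <- dim(shift$dphi)
  excl <- border_exclusion(d, config$excluded_border)
  excl[reference_rows, ] <- TRUE  # white strip is not tissue

  pred <- NULL; metrics <- NULL
  if (!is.null(mask)) {
    model <- train_threshold(shift, mask,
                             excluded_border = config$excluded_border,
                             exclude = excl)
  }
  if (!is.null(model)) {
    pred <- classify(shift, model)
    pred[excl] <- 0L
    if (!is.null(mask)) {
      cc <- confusion(pred, mask, exclude = excl)
      metrics <- metrics_row(sample_id, cc)
      utils::write.csv(metrics,
                       file.path(config$output_dir, "metrics.csv"),
                       row.names = FALSE)
    }
    write_mask(pred, file.path(config$output_dir, "predicted_mask.png"))
  }
  for (nm in c("blue", "red")) {
    pm <- get(nm)
    ph_cube <- spectral_cube(array(pm$phase, c(d, 1)), pm$wavelength_nm)
    write_envi_cube(ph_cube,
                    file.path(config$output_dir,
                              sprintf("phase_%s.raw", nm)),
                    file.path(config$output_dir,
                              sprintf("phase_%s.hdr", nm)))
  }
  shift_cube <- spectral_cube(array(shift$dphi, c(d, 1)), 1)
  write_envi_cube(shift_cube, file.path(config$output_dir, "dphi.raw"),
                  file.path(config$output_dir, "dphi.hdr"))
  .write_manifest(config$output_dir, "run", config,
                  list(sample_id = sample_id,
                       blue_nm = blue$wavelength_nm,
                       red_nm = red$wavelength_nm,
                       trained = !is.null(mask)))
  list(blue = blue, red = red, shift = shift, model = model,
       pred = pred, metrics = metrics, dir = config$output_dir)
}

#' Aggregate per-sample metrics CSVs into one table with a mean row
#'
#' @param metrics_csvs character vector of CSV paths (each as written
#'   by [pipeline_run()], or any CSV with a `sample_id` column and
#'   numeric metric columns).
#' @param out_csv optional path for the merged table.
#' @return data.frame: all rows plus a final `"Mean"` row (3 decimals).
#' @export
pipeline_report <- function(metrics_csvs, out_csv = NULL) {
  if (length(metrics_csvs) < 1L) stop("need at least one metrics CSV")
  rows <- do.call(rbind, lapply(metrics_csvs, function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop(sprintf("empty metrics CSV: %s", p))
    df$sample_id <- as.character(df$sample_id)
    df
  }))
  tab <- metrics_table(rows)
  if (!is.null(out_csv))
    utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
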