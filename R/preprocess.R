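#' White-reference normalization
#'
#' Divides a band image elementwise by a reference image of the same
#' shape, regularized so zero-valued reference pixels cannot produce
#' infinities: `out = image / pmax(reference, epsilon)`. Over a flat
#' white-paper region the output is ~1 by construction.
#'
#' @param image numeric matrix.
#' @param reference_image numeric matrix, same shape, values >= 0.
#' @param epsilon small positive regularizer (default 1e-6).
#' @return normalized matrix.
#' @export
white_normalize <- function(image, reference_image, epsilon = 1e-6) {
  if (!identical(dim(image), dim(reference_image)))
    stop("image and reference must have the same shape")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  if (any(reference_image < 0)) stop("reference intensities must be >= 0")
  image / pmax(reference_image, epsilon)
}

# round half away from zero (base round() is banker's)
.round_half_up <- function(x) floor(x + 0.5)

#' Histogram equalization onto 256 levels
#'
#' Standard cumulative-histogram equalization: each pixel is mapped to
#' `round(ecdf(v) * 255)`. The mapping is monotone and depends only on
#' the rank distribution of the input, so it is invariant under strictly
#' increasing intensity transforms. A constant image stays constant
#' (single occupied level).
#'
#' @param image finite numeric matrix.
#' @return integer matrix with values in 0..255.
#' @export
hist_equalize <- function(image) {
  if (!all(is.finite(image))) stop("input must be finite")
  v <- as.vector(image)
  cdf <- ecdf(v)(v)            # P(X <= v), in (0, 1]
  out <- .round_half_up(cdf * 255)
  matrix(as.integer(out), nrow = nrow(image))
}

#' Rescale an image to integer levels 0..255
#'
#' Affine min/max rescale with round-half-up; a constant image maps to
#' all zeros.
#'
#' @param image finite numeric matrix.
#' @return integer matrix with values in 0..255.
#' @export
normalize_levels <- function(image) {
  if (!all(is.finite(image))) stop("input must be finite")
  rng <- range(image)
  if (rng[1] == rng[2])
    return(matrix(0L, nrow(image), ncol(image)))
  out <- .round_half_up((image - rng[1]) / (rng[2] - rng[1]) * 255)
  matrix(as.integer(out), nrow = nrow(image))
}

# symmetric (edge-including) reflective pad by (pr, pc) on each side;
# requires pr < nrow, pc < ncol
.pad_reflect <- function(image, pr, pc) {
  nr <- nrow(image); nc <- ncol(image)
  ridx <- c(rev(seq_len(pr)), seq_len(nr), nr:(nr - pr + 1L))
  if (pr == 0L) ridx <- seq_len(nr)
  cidx <- c(rev(seq_len(pc)), seq_len(nc), nc:(nc - pc + 1L))
  if (pc == 0L) cidx <- seq_len(nc)
  image[ridx, cidx, drop = FALSE]
}

#' Moving-average (mean) filter
#'
#' Replaces each pixel by the mean of the `n x m` window centered on it,
#' `out(x, y) = (1/(n*m)) * sum over the window of the input`. Borders
#' are handled by symmetric reflective padding (edge row/column
#' mirrored including itself), so the output has the input's shape.
#'
#' @param image numeric matrix.
#' @param n,m odd positive window dimensions (rows, cols); default 3x3.
#' @return filtered matrix.
#' @export
moving_average <- function(image, n = 3L, m = 3L) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 1L || m < 1L || n %% 2L == 0L || m %% 2L == 0L)
    stop("window dimensions must be odd positive integers")
  pr <- (n - 1L) %/% 2L; pc <- (m - 1L) %/% 2L
  if (pr >= nrow(image) || pc >= ncol(image))
    stop("window larger than image")
  padded <- .pad_reflect(image, pr, pc)
  nr <- nrow(image); nc <- ncol(image)
  acc <- matrix(0, nr, nc)
  for (dr in seq_len(n) - 1L)
    for (dc in seq_len(m) - 1L)
      acc <- acc + padded[dr + seq_len(nr), dc + seq_len(nc), drop = FALSE]
  acc / (n * m)
}

#' Preprocessing configuration
#'
#' Bundles the tunables of the preprocessing chain. `stages` lists the
#' steps applied, in order, by [preprocess_image()]. The full
#' enhancement chain (used for display and overlays) is
#' `white_normalize -> hist_equalize -> normalize_levels ->
#' moving_average`; the phase-extraction chain defaults to the linear
#' subset `white_normalize -> moving_average` because equalization and
#' level quantization are nonlinear intensity maps that distort the
#' carrier waveform the phase demodulator relies on.
#'
#' @param ma_window length-2 odd integer vector (rows, cols), default 3x3.
#' @param reference_strategy `"strip_mean"` (per-column mean over the
#'   white strip rows) or `"reference_cube"` (a separately acquired
#'   reference cube).
#' @param epsilon division regularizer (> 0).
#' @param stages character vector drawn from
#'   `c("white_normalize", "hist_equalize", "normalize_levels",
#'   "moving_average")`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(ma_window = c(3L, 3L),
                              reference_strategy = c("strip_mean",
                                                     "reference_cube"),
                              epsilon = 1e-6,
                              stages = c("white_normalize",
                                         "moving_average")) {
  reference_strategy <- match.arg(reference_strategy)
  ma_window <- as.integer(ma_window)
  if (length(ma_window) != 2L || any(ma_window < 1L) ||
      any(ma_window %% 2L == 0L))
    stop("`ma_window` must be two odd positive integers")
  if (epsilon <= 0) stop("`epsilon` must be positive")
  allowed <- c("white_normalize", "hist_equalize", "normalize_levels",
               "moving_average")
  if (!all(stages %in% allowed))
    stop("unknown stage in `stages`")
  structure(list(ma_window = ma_window,
                 reference_strategy = reference_strategy,
                 epsilon = epsilon, stages = stages),
            class = "preprocess_config")
}

#' Apply the preprocessing chain to one band image
#'
#' Runs the stages named in `config$stages` in order. The
#' white-normalization stage needs `reference_image`; omitting it skips
#' that stage with a warning.
#'
#' @param image numeric matrix.
#' @param reference_image matrix matching `image`, or `NULL`.
#' @param config a [preprocess_config()].
#' @return processed matrix (numeric; integer-valued after the
#'   quantizing stages).
#' @export
preprocess_image <- function(image, reference_image = NULL,
                             config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  out <- image
  for (stage in config$stages) {
    out <- switch(stage,
      white_normalize = {
        if (is.null(reference_image)) {
          warning("no reference image; skipping white normalization")
          out
        } else white_normalize(out, reference_image, config$epsilon)
      },
      hist_equalize = hist_equalize(out),
      normalize_levels = normalize_levels(out),
      moving_average = moving_average(out, config$ma_window[1],
                                      config$ma_window[2])
    )
    out <- out * 1.0
  }
  out
}
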