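#' Train a pixelwise phase-shift threshold classifier
#'
#' Pools the labeled `dphi` values of one or more phase-shift maps and
#' sweeps every candidate cut (midpoints between consecutive distinct
#' pooled values, plus sentinels just outside the data range) for both
#' polarities, choosing the threshold that maximizes the Youden index
#' `J = Sen + Spec - 1`. Ties are broken toward the lower threshold.
#' Deterministic given the inputs.
#'
#' @param shift_maps a [phase_shift_map()] or list of them (bare
#'   matrices accepted).
#' @param masks matching 0/1 truth mask or list of masks.
#' @param excluded_border fraction of columns at each image edge
#'   excluded from training (phase edge artifacts; default 0.02).
#' @param exclude optional logical matrix (or list of them, one per
#'   map), `TRUE` = drop from training in addition to the border
#'   (e.g. the white-reference strip, which carries no tissue signal).
#' @return an object of class `threshold_model` with fields
#'   `threshold`, `polarity` (`"tumor_above"` or `"tumor_below"`),
#'   `youden_j`, `uninformative` flag, `band_pair`, `trained_on`.
#' @export
train_threshold <- function(shift_maps, masks, excluded_border = 0.02,
                            exclude = NULL) {
  if (inherits(shift_maps, "phase_shift_map") || is.matrix(shift_maps))
    shift_maps <- list(shift_maps)
  if (is.matrix(masks)) masks <- list(masks)
  if (is.matrix(exclude) || is.null(exclude))
    exclude <- rep(list(exclude), length(shift_maps))
  if (length(shift_maps) < 1L || length(shift_maps) != length(masks))
    stop("need the same positive number of maps and masks")
  pair <- NA_real_
  feats <- numeric(0); labs <- integer(0)
  for (i in seq_along(shift_maps)) {
    sm <- shift_maps[[i]]
    d <- if (inherits(sm, "phase_shift_map")) sm$dphi else sm
    if (inherits(sm, "phase_shift_map")) pair <- sm$pair
    msk <- masks[[i]]
    if (!identical(dim(d), dim(msk)))
      stop("map and mask shapes differ")
    keep <- !border_exclusion(dim(d), excluded_border)
    if (!is.null(exclude[[i]])) keep <- keep & !exclude[[i]]
    feats <- c(feats, d[keep])
    labs <- c(labs, as.integer(msk[keep]))
  }
  if (length(unique(labs)) < 2L)
    stop("training masks must contain both classes")

  sweep <- .sweep_youden(feats, labs)
  model <- structure(
    list(threshold = sweep$threshold, polarity = sweep$polarity,
         youden_j = sweep$j, uninformative = sweep$j < 0.05,
         band_pair = pair, excluded_border = excluded_border,
         trained_on = sprintf("map_%d", seq_along(shift_maps))),
    class = "threshold_model")
  if (model$uninformative)
    warning("trained model is uninformative (Youden J < 0.05)")
  model
}

# Exhaustive Youden sweep; candidates are midpoints between consecutive
# distinct sorted values plus sentinels outside the data range; rule is
# value > t (tumor_above) or value < t (tumor_below). J values derive
# from integer counts, so exact-equality tie handling is well defined:
# maximum J, then lowest threshold, then tumor_above.
.sweep_youden <- function(feats, labs) {
  ord <- order(feats)
  f <- feats[ord]; l <- labs[ord]
  n <- length(f)
  n_pos <- sum(l == 1L); n_neg <- n - n_pos
  cum_pos <- cumsum(l == 1L)
  boundary <- which(diff(f) > 0)         # f[i] < f[i+1]
  cand_idx <- c(0L, boundary, n)         # pixels <= candidate
  thr <- c(f[1] - 1, (f[boundary] + f[boundary + 1L]) / 2, f[n] + 1)
  pos_below <- c(0, cum_pos)[cand_idx + 1L]
  neg_below <- cand_idx - pos_below
  j_a <- (n_pos - pos_below) / n_pos + neg_below / n_neg - 1
  best_a <- which(j_a == max(j_a))[1L]
  best_b <- which(j_a == min(j_a))[1L]   # J(tumor_below) = -J(tumor_above)
  if (max(j_a) >= -min(j_a) &&
      !(max(j_a) == -min(j_a) && thr[best_b] < thr[best_a])) {
    out <- list(j = max(j_a), threshold = thr[best_a],
                polarity = "tumor_above")
  } else {
    out <- list(j = -min(j_a), threshold = thr[best_b],
                polarity = "tumor_below")
  }
  out$threshold <- max(0, min(pi, out$threshold))
  out
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> dphi %s %.4f rad (J = %.3f%s), pair %.1f / %.1f nm\n",
    if (x$polarity == "tumor_above") ">" else "<",
    x$threshold, x$youden_j,
    if (x$uninformative) "; UNINFORMATIVE" else "",
    x$band_pair[1], x$band_pair[2]))
  invisible(x)
}

#' Logical matrix of excluded border columns
#'
#' Marks the first and last `fraction` of columns (rounded down) of an
#' image as excluded; phase estimates there carry demodulation edge
#' artifacts.
#'
#' @param dims `c(rows, cols)`.
#' @param fraction per-side fraction of columns (default 0.02).
#' @return logical matrix, `TRUE` = excluded.
#' @export
border_exclusion <- function(dims, fraction = 0.02) {
  excl <- matrix(FALSE, dims[1], dims[2])
  nb <- floor(dims[2] * fraction)
  if (nb > 0) {
    excl[, seq_len(nb)] <- TRUE
    excl[, dims[2] - seq_len(nb) + 1L] <- TRUE
  }
  excl
}

#' Classify a phase-shift map with a trained threshold model
#'
#' A pixel is labeled tumor iff its `dphi` lies strictly on the tumor
#' side of the threshold (values equal to the threshold are normal).
#' No spatial postprocessing is applied.
#'
#' @param shift_map a [phase_shift_map()] or matrix.
#' @param model a [train_threshold()] model.
#' @return 0/1 integer matrix.
#' @export
classify <- function(shift_map, model) {
  stopifnot(inherits(model, "threshold_model"))
  d <- if (inherits(shift_map, "phase_shift_map")) shift_map$dphi
       else shift_map
  pred <- if (model$polarity == "tumor_above") d > model$threshold
          else d < model$threshold
  matrix(as.integer(pred), nrow(d))
}

#' Pixelwise confusion counts
#'
#' Tallies TP/FP/TN/FN between a predicted and a truth mask over the
#' non-excluded pixels.
#'
#' @param pred,truth 0/1 matrices of the same shape.
#' @param exclude optional logical matrix, `TRUE` = drop from tally.
#' @return object of class `confusion_counts` (fields TP, FP, TN, FN).
#' @export
confusion <- function(pred, truth, exclude = NULL) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ")
  keep <- if (is.null(exclude)) rep(TRUE, length(pred))
          else {
            if (!identical(dim(exclude), dim(pred)))
              stop("exclude region shape differs")
            !as.vector(exclude)
          }
  p <- as.vector(pred)[keep]; t <- as.vector(truth)[keep]
  structure(list(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
                 TN = sum(p == 0 & t == 0), FN = sum(p == 0 & t == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

.check_counts <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  invisible(c)
}

#' Sensitivity TP / (TP + FN)
#' @param c a [confusion()] result.
#' @return fraction in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  .check_counts(c)
  if (c$TP + c$FN == 0) stop("sensitivity undefined: TP + FN == 0")
  c$TP / (c$TP + c$FN)
}

#' Specificity TN / (TN + FP)
#' @param c a [confusion()] result.
#' @return fraction in `[0, 1]`.
#' @export
specificity <- function(c) {
  .check_counts(c)
  if (c$TN + c$FP == 0) stop("specificity undefined: TN + FP == 0")
  c$TN / (c$TN + c$FP)
}

#' Accuracy (TP + TN) / total
#' @param c a [confusion()] result.
#' @return fraction in `[0, 1]`.
#' @export
accuracy <- function(c) {
  .check_counts(c)
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("accuracy undefined: no evaluated pixels")
  (c$TP + c$TN) / total
}

#' Build a per-sample metrics row
#'
#' Converts confusion counts into percentage metrics; the FN and FP
#' ratios are the exact complements of sensitivity and specificity, so
#' `sen_pct + fn_ratio_pct == 100` and `spec_pct + fp_ratio_pct == 100`
#' hold by construction.
#'
#' @param sample_id identifier.
#' @param c a [confusion()] result.
#' @return one-row data.frame with columns `sample_id`, `sen_pct`,
#'   `spec_pct`, `fn_ratio_pct`, `fp_ratio_pct`, `accuracy_pct`.
#' @export
metrics_row <- function(sample_id, c) {
  sen <- 100 * sensitivity(c); spec <- 100 * specificity(c)
  data.frame(sample_id = as.character(sample_id),
             sen_pct = sen, spec_pct = spec,
             fn_ratio_pct = 100 - sen, fp_ratio_pct = 100 - spec,
             accuracy_pct = 100 * accuracy(c),
             stringsAsFactors = FALSE)
}

#' Metrics table with a mean row
#'
#' Stacks per-sample metric rows and appends the arithmetic column
#' means as a final `"Mean"` row, reported to 3 decimals.
#'
#' @param rows data.frame of metric rows (as from [metrics_row()], or
#'   any data.frame with a `sample_id` column and numeric metric
#'   columns).
#' @return data.frame with the mean row appended.
#' @export
metrics_table <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1)
  num_cols <- names(rows)[vapply(rows, is.numeric, TRUE)]
  mean_row <- rows[1, , drop = FALSE]
  for (nm in names(rows))
    mean_row[[nm]] <- if (nm %in% num_cols)
      round(mean(rows[[nm]]), 3) else "Mean"
  rbind(rows, mean_row)
}

#' Alpha-blend a tumor mask over an RGB image
#'
#' @param mask 0/1 matrix.
#' @param rgb_image rows x cols x 3 array in `[0, 1]` (a grayscale
#'   matrix is broadcast to RGB).
#' @param alpha blend weight in `[0, 1]` (0 leaves the base unchanged).
#' @param color length-3 RGB triplet for tumor pixels (default red).
#' @return rows x cols x 3 array.
#' @export
overlay <- function(mask, rgb_image, alpha = 0.5, color = c(1, 0, 0)) {
  if (is.matrix(rgb_image))
    rgb_image <- array(rep(rgb_image, 3),
                       dim = c(dim(rgb_image), 3))
  if (!identical(dim(rgb_image)[1:2], dim(mask)))
    stop("mask and image shapes differ")
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  out <- rgb_image
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[mask == 1] <- (1 - alpha) * plane[mask == 1] + alpha * color[ch]
    out[, , ch] <- plane
  }
  out
}

#' Per-specimen classification ratios of the reference benchmark
#'
#' Loads the bundled table of per-specimen pixelwise classification
#' ratios (Sen, Spec, FN ratio, FP ratio, in percent) reported for ten
#' pathologist-stained ex-vivo breast specimens evaluated at 632 nm.
#' Used as the package's reference benchmark for the metrics
#' machinery.
#'
#' @return data.frame with columns `sample_id`, `sen_pct`, `spec_pct`,
#'   `fn_ratio_pct`, `fp_ratio_pct`.
#' @export
stained_specimen_ratios <- function() {
  path <- system.file("extdata", "stained_specimen_ratios.csv",
                      package = "mwiphase", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character"))
}
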