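# Independent brute-force oracles and small fixtures used across tests.

# quadrature-demodulation oracle for the global phase offset of a line
# assumed to be a * cos(2*pi*f*x/N + phi0): multiply by cos/sin at the
# known carrier, ideal low-pass (full-line mean), atan2
quadrature_phi0 <- function(line, f) {
  n <- length(line)
  theta <- 2 * pi * f * (0:(n - 1)) / n
  i_comp <- mean(line * cos(theta))
  q_comp <- mean(line * sin(theta))
  atan2(-q_comp, i_comp)
}

# double-loop window mean with symmetric (edge-including) reflection
brute_moving_average <- function(img, n, m) {
  nr <- nrow(img); nc <- ncol(img)
  pr <- (n - 1) %/% 2; pc <- (m - 1) %/% 2
  reflect <- function(i, nmax) {
    if (i < 1) 1 - i else if (i > nmax) 2 * nmax + 1 - i else i
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    s <- 0
    for (dr in -pr:pr) for (dc in -pc:pc) {
      s <- s + img[reflect(r + dr, nr), reflect(cl + dc, nc)]
    }
    out[r, cl] <- s / (n * m)
  }
  out
}

# exhaustive double-loop Youden sweep; same candidate definition and
# tie rules as the implementation contract: midpoints between distinct
# sorted values plus sentinels; max J, then lowest threshold, then
# tumor_above
brute_youden <- function(feats, labs) {
  u <- sort(unique(feats))
  cand <- if (length(u) > 1) {
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  } else c(u - 1, u + 1)
  n_pos <- sum(labs == 1); n_neg <- sum(labs == 0)
  best <- NULL
  for (t in cand) {
    for (pol in c("tumor_above", "tumor_below")) {
      pred <- if (pol == "tumor_above") feats > t else feats < t
      j <- sum(pred & labs == 1) / n_pos +
        sum(!pred & labs == 0) / n_neg - 1
      better <- is.null(best) || j > best$j ||
        (j == best$j && t < best$threshold) ||
        (j == best$j && t == best$threshold &&
           pol == "tumor_above" && best$polarity == "tumor_below")
      if (better) best <- list(j = j, threshold = t, polarity = pol)
    }
  }
  best$threshold <- max(0, min(pi, best$threshold))
  best
}

# binary erosion of a logical mask by Chebyshev radius k
erode_mask <- function(mask, k) {
  er <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -k:k) for (dc in -k:k) {
    sh <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    sh[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
    er <- er & sh
  }
  er
}

# compact two-band phantom scene for fast tests
small_scene <- function(noise_sigma = 0.02, seed = 11,
                        tumor_regions = list(c(36, 40, 10, 12, 7))) {
  phantom_scene(rows = 64, cols = 80,
                wavelengths_nm = c(446.6, 632),
                reference_strip = c(0L, 7L),
                tumor_regions = tumor_regions,
                carrier_cycles = 8,
                noise_sigma = noise_sigma, seed = seed)
}

# indices of a scene's white strip as 1-based rows
strip_rows <- function(scene) (scene$reference_strip[1]:scene$reference_strip[2]) + 1L
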