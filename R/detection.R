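# Fluorescent cell detection: robust intensity threshold, connected
# components, area/roundness/SNR filters, and two-channel starter
# classification by centroid overlap. All thresholds are user-adjustable via
# detection_params(); the defaults are declared package choices.

#' Detection parameter set
#'
#' @param min_area_px,max_area_px component area bounds in pixels.
#' @param min_circularity minimum isoperimetric circularity 4*pi*A/P^2 in
#'   `[0, 1]`.
#' @param min_snr minimum signal-to-noise ratio: background-subtracted
#'   component mean over the robust background sd.
#' @param threshold_k intensity threshold = background median +
#'   `threshold_k` * 1.4826 * MAD.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma applied before
#'   thresholding (matched filtering); 0 disables. Suppresses noise-ragged
#'   component boundaries that would otherwise deflate circularity.
#' @param max_overlap_dist_px centroid distance below which a helper/rabies
#'   pair is called one starter cell.
#' @return a `detection_params` list.
#' @export
detection_params <- function(min_area_px = 20L, max_area_px = 500L,
                             min_circularity = 0.4, min_snr = 3,
                             threshold_k = 5, smooth_sigma_px = 1,
                             max_overlap_dist_px = 5) {
  stopifnot(min_area_px > 0, min_area_px < max_area_px,
            min_circularity >= 0, min_circularity <= 1,
            min_snr > 0, smooth_sigma_px >= 0, max_overlap_dist_px >= 0)
  structure(list(min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 min_circularity = min_circularity, min_snr = min_snr,
                 threshold_k = threshold_k, smooth_sigma_px = smooth_sigma_px,
                 max_overlap_dist_px = max_overlap_dist_px),
            class = "detection_params")
}

# separable Gaussian smoothing with replicate padding
gaussian_smooth <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(image); w <- ncol(image)
  conv_rows <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(image))))
}

#' Isoperimetric circularity
#'
#' `min(1, 4*pi*area / perimeter^2)`: 1 for an ideal disk, smaller for
#' elongated or ragged shapes.
#'
#' @param area_px area in pixels.
#' @param perimeter_px perimeter in pixels (> 0).
#' @return circularity in `(0, 1]`.
#' @export
circularity <- function(area_px, perimeter_px) {
  if (any(perimeter_px <= 0)) stop("perimeter must be positive")
  pmin(1, 4 * pi * area_px / perimeter_px^2)
}

# 8-connected component labelling by iterative minimum-label propagation.
# Vectorized over the whole image; converges in O(component diameter) passes,
# which is small for blob-like cells.
label_components <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  lab[bin] <- seq_len(sum(bin))
  pad_shift <- function(m, dr, dc) {
    out <- matrix(0L, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    new_lab <- lab
    for (s in shifts) {
      nb <- pad_shift(lab, s[1], s[2])
      take <- bin & nb > 0L & (new_lab == 0L | nb < new_lab)
      new_lab[take] <- nb[take]
    }
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # relabel to consecutive 1..k
  u <- sort(unique(lab[lab > 0L]))
  if (length(u)) lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# crack-length perimeter per labelled component, corrected by pi/4 so a
# digitized disk scores ~2*pi*r (raw 4-neighbour crack length overestimates
# smooth contours by ~4/pi)
component_perimeters <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  exposed <- matrix(0L, h, w)
  neighbor_differs <- function(dr, dc) {
    nb <- matrix(-1L, h, w)  # outside image counts as exposed edge
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    nb[rs, cs] <- lab[rs - dr, cs - dc]
    (lab > 0L) & (nb != lab)
  }
  for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    exposed <- exposed + neighbor_differs(s[1], s[2])
  }
  crack <- tapply(exposed[lab > 0L], lab[lab > 0L], sum)
  crack * pi / 4
}

#' Detect fluorescent cells in one channel image
#'
#' Thresholds the image at background median + `threshold_k` robust sd
#' (1.4826 * MAD), labels 8-connected components, and keeps those passing
#' the area, circularity and SNR filters. Centroids are intensity-weighted.
#'
#' @param image numeric matrix, finite and non-negative.
#' @param params a [detection_params()].
#' @param channel channel label stored on the detections (`"helper"` or
#'   `"rabies"`).
#' @return data.frame of detections (`x`, `y` 0-based centroid, `area_px`,
#'   `circularity`, `snr`, `mean_intensity`, `channel`), sorted by
#'   descending mean intensity.
#' @export
detect_cells <- function(image, params = detection_params(),
                         channel = "rabies") {
  stopifnot(is.matrix(image), inherits(params, "detection_params"))
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  if (any(image < 0)) stop("image contains negative pixels")

  image <- gaussian_smooth(image, params$smooth_sigma_px)
  bg_med <- stats::median(image)
  bg_sd <- stats::mad(image)  # 1.4826 * MAD, consistent estimator
  thr <- bg_med + params$threshold_k * bg_sd
  bin <- image > thr
  empty <- data.frame(x = numeric(0), y = numeric(0), area_px = integer(0),
                      circularity = numeric(0), snr = numeric(0),
                      mean_intensity = numeric(0), channel = character(0))
  if (!any(bin)) return(empty)
  # background stats from sub-threshold pixels only (robust to bright cells)
  bg_pix <- image[!bin]
  bg_med <- stats::median(bg_pix)
  bg_sd <- stats::mad(bg_pix)
  if (bg_sd == 0) bg_sd <- .Machine$double.eps

  lab <- label_components(bin)
  k <- max(lab)
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1) %% nrow(image) + 1
  cols <- (idx - 1) %/% nrow(image) + 1
  inten <- image[idx]
  area <- tabulate(l, k)
  wsum <- tapply(inten, l, sum)
  cx <- tapply(inten * cols, l, sum) / wsum
  cy <- tapply(inten * rows, l, sum) / wsum
  mean_int <- wsum / area
  perim <- component_perimeters(lab)
  circ <- circularity(area, pmax(perim, .Machine$double.eps))
  snr <- (mean_int - bg_med) / bg_sd

  keep <- area >= params$min_area_px & area <= params$max_area_px &
    circ >= params$min_circularity & snr >= params$min_snr
  out <- data.frame(x = as.numeric(cx)[keep] - 1, y = as.numeric(cy)[keep] - 1,
                    area_px = area[keep],
                    circularity = as.numeric(circ)[keep],
                    snr = as.numeric(snr)[keep],
                    mean_intensity = as.numeric(mean_int)[keep],
                    channel = rep(channel, sum(keep)))
  out <- out[order(-out$mean_intensity, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify starter vs presynaptic cells by two-channel centroid overlap
#'
#' Greedy one-to-one matching of rabies and helper detections in ascending
#' centroid-distance order. A matched pair within `max_dist_px` is one
#' starter cell (reported at the rabies centroid); unmatched rabies
#' detections are presynaptic; unmatched helper detections are helper-only.
#'
#' @param helper,rabies detection data.frames from [detect_cells()] (need
#'   columns `x`, `y`).
#' @param max_dist_px maximum centroid distance for a starter call.
#' @return data.frame of cell calls: `x`, `y`, `kind` in
#'   `{starter, presynaptic, helper_only}`, `region_id` (NA until assigned).
#' @export
classify_starters <- function(helper, rabies, max_dist_px = 5) {
  stopifnot(max_dist_px >= 0)
  nh <- nrow(helper); nr <- nrow(rabies)
  matched_h <- rep(FALSE, nh); matched_r <- rep(FALSE, nr)
  pair_r <- integer(0); pair_h <- integer(0)
  if (nh > 0 && nr > 0) {
    d <- outer(rabies$x, helper$x, `-`)^2 + outer(rabies$y, helper$y, `-`)^2
    ord <- order(d)
    for (o in ord) {
      if (d[o] > max_dist_px^2) break
      ri <- (o - 1) %% nr + 1
      hi <- (o - 1) %/% nr + 1
      if (!matched_r[ri] && !matched_h[hi]) {
        matched_r[ri] <- TRUE; matched_h[hi] <- TRUE
        pair_r <- c(pair_r, ri); pair_h <- c(pair_h, hi)
      }
    }
  }
  calls <- rbind(
    if (length(pair_r)) data.frame(x = rabies$x[pair_r], y = rabies$y[pair_r],
                                   kind = "starter"),
    if (any(!matched_r)) data.frame(x = rabies$x[!matched_r],
                                    y = rabies$y[!matched_r],
                                    kind = "presynaptic"),
    if (any(!matched_h)) data.frame(x = helper$x[!matched_h],
                                    y = helper$y[!matched_h],
                                    kind = "helper_only")
  )
  if (is.null(calls)) {
    calls <- data.frame(x = numeric(0), y = numeric(0), kind = character(0))
  }
  calls$region_id <- NA_integer_
  calls <- calls[order(calls$kind, calls$x, calls$y), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}
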