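# Per-section planar registration from user landmark pairs, and mapping of
# cell calls into atlas labels and hemispheres. Transform family is affine:
# exact on 3 non-collinear landmarks, least squares beyond.

#' Construct a landmark set for one section
#'
#' @param pairs data.frame with columns `img_x`, `img_y`, `atlas_x`,
#'   `atlas_y` (0-based pixel coordinates); at least 3 rows, image points
#'   not all collinear.
#' @param section_id section identifier.
#' @param ap_mm section AP coordinate, mm from bregma.
#' @return a `landmark_set`.
#' @export
landmark_set <- function(pairs, section_id = "s1", ap_mm = 0) {
  req <- c("img_x", "img_y", "atlas_x", "atlas_y")
  stopifnot(is.data.frame(pairs), all(req %in% names(pairs)))
  if (nrow(pairs) < 3) stop("degenerate landmarks: need at least 3 pairs")
  p <- cbind(pairs$img_x, pairs$img_y)
  sv <- svd(scale(p, scale = FALSE))$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate landmarks: image points are collinear")
  }
  structure(list(pairs = pairs[, req], section_id = section_id,
                 ap_mm = as.numeric(ap_mm)),
            class = "landmark_set")
}

#' Fit a least-squares affine transform from landmarks
#'
#' Minimizes the sum of squared atlas-space residuals. With exactly 3
#' non-collinear pairs the fit interpolates (rms 0); with more it is the
#' normal-equations least-squares solution.
#'
#' @param landmarks a [landmark_set()].
#' @return a `planar_transform`: 2x3 coefficient matrix `matrix` (rows =
#'   atlas x/y, columns = img_x, img_y, 1) and `rms_residual_px`.
#' @export
fit_affine <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  p <- landmarks$pairs
  X <- cbind(p$img_x, p$img_y, 1)
  Y <- cbind(p$atlas_x, p$atlas_y)
  coef <- qr.solve(X, Y)           # 3x2
  m <- t(coef)                     # 2x3
  if (abs(det(m[, 1:2])) < 1e-12) stop("fitted affine is singular")
  fitted <- X %*% coef
  rms <- sqrt(mean(rowSums((Y - fitted)^2)))
  structure(list(matrix = m, rms_residual_px = rms), class = "planar_transform")
}

#' Apply a planar transform to points
#'
#' @param transform a `planar_transform`.
#' @param xy matrix or data.frame with two columns (x, y), 0-based.
#' @return two-column matrix of transformed points.
#' @export
apply_transform <- function(transform, xy) {
  stopifnot(inherits(transform, "planar_transform"))
  xy <- as.matrix(xy)
  cbind(xy, 1) %*% t(transform$matrix)
}

#' Analytic inverse of a planar transform
#'
#' @param transform a `planar_transform`.
#' @return the inverse `planar_transform`.
#' @export
invert_transform <- function(transform) {
  A <- transform$matrix[, 1:2]
  b <- transform$matrix[, 3]
  Ai <- solve(A)
  structure(list(matrix = cbind(Ai, -Ai %*% b), rms_residual_px = 0),
            class = "planar_transform")
}

#' Assign atlas regions and hemispheres to cell calls
#'
#' Maps each centroid through the transform, rounds to the nearest atlas
#' pixel, and reads the label mask. Points landing outside the mask or on
#' background get region 0 ("unassigned"). Hemisphere is `left` when the
#' mapped x is below `midline_x`, `right` above; points exactly on the
#' midline take the section's declared `side`.
#'
#' @param calls data.frame from [classify_starters()] (columns `x`, `y`).
#' @param transform a `planar_transform` (image -> atlas pixels).
#' @param slice an `atlas_slice`.
#' @param side declared side of the imaged hemisphere (`"left"`/`"right"`),
#'   used only for exact midline ties.
#' @return `calls` with `region_id` and `hemisphere` filled; same row count.
#' @export
assign_regions <- function(calls, transform, slice, side = "left") {
  stopifnot(inherits(slice, "atlas_slice"), side %in% c("left", "right"))
  if (nrow(calls) == 0) {
    calls$region_id <- integer(0)
    calls$hemisphere <- character(0)
    return(calls)
  }
  mapped <- apply_transform(transform, calls[, c("x", "y")])
  col1 <- round(mapped[, 1]) + 1  # 0-based x -> 1-based column
  row1 <- round(mapped[, 2]) + 1
  mask <- slice$label_mask
  inside <- row1 >= 1 & row1 <= nrow(mask) & col1 >= 1 & col1 <= ncol(mask)
  region <- rep(0L, nrow(calls))
  region[inside] <- mask[cbind(row1[inside], col1[inside])]
  calls$region_id <- region
  hemi <- ifelse(mapped[, 1] < slice$midline_x, "left",
                 ifelse(mapped[, 1] > slice$midline_x, "right", side))
  calls$hemisphere <- hemi
  calls
}
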