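#' Grayscale ROI image
#'
#' A small square patch (default 10 x 10 um) of a confocal plane, stored as
#' a numeric matrix with rows indexing y and columns indexing x; the x axis
#' is the culture's long axis.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_pitch um per pixel (default 0.25, i.e. 40 x 40 px per
#'   10 um ROI).
#' @return An object of class `roi_image`.
#' @export
roi_image <- function(pixels, pixel_pitch = 0.25) {
  pixels <- as.matrix(pixels)
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  structure(list(pixels = pixels, pixel_pitch = pixel_pitch),
            class = "roi_image")
}

#' Full 2D cross-correlation of two binary images
#'
#' `C(k, l) = sum_{m,n} X(m, n) * Y(m - k, n - l)` with zero padding
#' outside the supports, for all shifts `k in -(M-1)..(M-1)`,
#' `l in -(N-1)..(N-1)`. The central element of the `(2M-1) x (2N-1)`
#' result equals `sum(X * Y)`.
#'
#' @param X,Y equal-shape matrices with values in `{0, 1}`.
#' @return The correlation surface matrix.
#' @export
xcorr2d <- function(X, Y) {
  X <- as.matrix(X) * 1.0
  Y <- as.matrix(Y) * 1.0
  if (!all(dim(X) == dim(Y))) stop("images must have identical dimensions")
  if (!all(X %in% c(0, 1)) || !all(Y %in% c(0, 1)))
    stop("images must be binary (0/1)")
  cpp_xcorr2d(X, Y)
}

erode_cross <- function(mask) {
  # binary erosion with a 3x3 cross; outside the image counts as background
  m <- nrow(mask); n <- ncol(mask)
  pad <- matrix(FALSE, m + 2, n + 2)
  pad[2:(m + 1), 2:(n + 1)] <- mask
  pad[2:(m + 1), 2:(n + 1)] &
    pad[1:m, 2:(n + 1)] & pad[3:(m + 2), 2:(n + 1)] &
    pad[2:(m + 1), 1:n] & pad[2:(m + 1), 3:(n + 2)]
}

perimeter_points <- function(mask) {
  # pixels of the mask with at least one 4-neighbour outside it
  edge <- mask & !erode_cross(mask)
  which(edge, arr.ind = TRUE)
}

wrap_angle <- function(deg) {
  # fold into (-90, 90]
  a <- ((deg + 90) %% 180) - 90
  ifelse(a == -90, 90, a)
}

#' ROI directionality by thresholded autocorrelation
#'
#' The ROI is binarised at `intensity_threshold`, autocorrelated
#' ([xcorr2d()] with itself), and the correlation surface binarised at
#' `surface_threshold_frac` of its maximum. The connected blob containing
#' the surface centre is extracted; its major axis is the maximum pairwise
#' distance between blob edge points, and its minor axis the shortest chord
#' through the major-axis midpoint between edge points. The ROI is
#' directional when the axis ratio is >= 2 and the major axis is >= 5 px;
#' the reported angle is the major-axis angle to the x axis (culture long
#' axis), degrees in (-90, 90], counter-clockwise positive.
#'
#' @param roi a [roi_image()] or plain matrix.
#' @param intensity_threshold grayscale binarisation threshold (default 55).
#' @param surface_threshold_frac fraction of the correlation maximum
#'   (default 0.70).
#' @return An object of class `directionality_result`: list with
#'   `directional`, `angle` (deg, `NA` when non-directional), `major_len`,
#'   `minor_len` (px), and `empty` (`TRUE` when nothing survives the
#'   intensity threshold).
#' @export
roi_directionality <- function(roi, intensity_threshold = 55,
                               surface_threshold_frac = 0.70) {
  px <- if (inherits(roi, "roi_image")) roi$pixels else as.matrix(roi)
  if (length(px) == 0) stop("roi is empty")
  X <- (px > intensity_threshold) * 1.0
  if (sum(X) == 0) {
    return(structure(list(directional = FALSE, angle = NA_real_,
                          major_len = NA_real_, minor_len = NA_real_,
                          empty = TRUE),
                     class = "directionality_result"))
  }
  C <- cpp_xcorr2d(X, X)
  # autocorrelation must be symmetric under 180-degree rotation
  stopifnot(isTRUE(all.equal(C, C[rev(seq_len(nrow(C))),
                                  rev(seq_len(ncol(C)))])))
  mask <- C >= surface_threshold_frac * max(C)
  lab <- cpp_label_components(as.vector(mask), dim(mask), 8L)
  center <- c(nrow(X), ncol(X)) # central element of the (2M-1)x(2N-1) surface
  blob <- matrix(lab == lab[center[1] + (center[2] - 1) * nrow(mask)],
                 nrow(mask), ncol(mask))
  edge <- perimeter_points(blob)
  if (nrow(edge) < 2) {
    return(structure(list(directional = FALSE, angle = NA_real_,
                          major_len = 0, minor_len = 0, empty = FALSE),
                     class = "directionality_result"))
  }
  # rows of `edge` are (row, col) = (y, x)
  mp <- cpp_max_pair_distance(cbind(edge[, 2], edge[, 1]))
  p1 <- edge[mp$i, ]; p2 <- edge[mp$j, ]
  major <- mp$distance
  mid <- (p1 + p2) / 2
  minor <- shortest_chord(edge, mid)
  directional <- is.finite(minor) && minor > 0 &&
    (major / minor >= 2) && (major >= 5)
  angle <- if (directional) {
    wrap_angle(atan2(p2[1] - p1[1], p2[2] - p1[2]) * 180 / pi)
  } else NA_real_
  structure(list(directional = directional, angle = angle,
                 major_len = major, minor_len = minor, empty = FALSE),
            class = "directionality_result")
}

shortest_chord <- function(edge, mid, tol = 0.75) {
  # shortest segment between two edge points passing within `tol` px of
  # `mid`; ties resolve to the shorter chord by construction
  n <- nrow(edge)
  best <- Inf
  for (i in seq_len(n - 1)) {
    p <- edge[i, ]
    for (j in (i + 1):n) {
      q <- edge[j, ]
      v <- q - p
      len2 <- sum(v^2)
      if (len2 == 0) next
      t <- sum((mid - p) * v) / len2
      if (t < 0 || t > 1) next
      perp <- mid - (p + t * v)
      if (sum(perp^2) <= tol^2) {
        len <- sqrt(len2)
        if (len < best) best <- len
      }
    }
  }
  if (is.infinite(best)) {
    # degenerate blob: fall back to twice the closest edge distance
    best <- 2 * sqrt(min(rowSums(sweep(edge, 2, mid)^2)))
  }
  best
}

#' @export
print.directionality_result <- function(x, ...) {
  if (x$directional)
    cat(sprintf("Directional ROI: angle %.1f deg (major %.1f px, minor %.1f px)\n",
                x$angle, x$major_len, x$minor_len))
  else
    cat("Non-directional ROI\n")
  invisible(x)
}

#' Nucleus major-axis angle and height from a 3D ROI
#'
#' Implements the morphometric pipeline for a manually outlined nucleus
#' bounding cuboid: (1) binarise (default threshold: midpoint of the
#' intensity range, recorded in the output), (2) suppress connected
#' components (3D, 6-connectivity) touching the lateral (x/y) border,
#' (3) erode each z-plane with a 3x3 cross, (4) extract each z-plane's
#' outline, (5) find the outline voxel pair at maximum 3D Euclidean
#' distance (the major axis), (6) report that axis' angle in the X-Y plane
#' relative to the x axis, and (7) report the z-range of the outline voxels
#' as the nucleus height.
#'
#' @param voxels 3D numeric array (x, y, z) of intensities.
#' @param voxel_size um per voxel, length 1 or 3 (x, y, z).
#' @param threshold binarisation level; default `(min + max) / 2`.
#' @return List with `angle` (deg in (-90, 90]), `height` (um),
#'   `major_len` (um), `low_anisotropy` flag, and `threshold` used.
#' @export
nucleus_axis_height <- function(voxels, voxel_size = 1, threshold = NULL) {
  stopifnot(length(dim(voxels)) == 3)
  vs <- if (length(voxel_size) == 1) rep(voxel_size, 3) else voxel_size
  stopifnot(length(vs) == 3, all(vs > 0))
  if (is.null(threshold))
    threshold <- (min(voxels) + max(voxels)) / 2
  mask <- voxels > threshold
  lab <- cpp_label_components(as.vector(mask), dim(mask), 6L)
  dim(lab) <- dim(mask)
  border_labels <- unique(c(lab[1, , ], lab[dim(lab)[1], , ],
                            lab[, 1, ], lab[, dim(lab)[2], ]))
  border_labels <- setdiff(border_labels, 0L)
  keep <- mask & !(lab %in% border_labels)
  dim(keep) <- dim(mask)
  if (!any(keep)) stop("nucleus touches border")
  outline <- array(FALSE, dim(keep))
  for (zi in seq_len(dim(keep)[3])) {
    plane <- erode_cross(keep[, , zi])
    outline[, , zi] <- plane & !erode_cross(plane)
  }
  pts_idx <- which(outline, arr.ind = TRUE)
  if (nrow(pts_idx) < 2) stop("nucleus vanished after erosion")
  pts <- sweep(pts_idx, 2, vs, `*`)
  mp <- cpp_max_pair_distance(pts)
  p1 <- pts[mp$i, ]; p2 <- pts[mp$j, ]
  angle <- wrap_angle(atan2(p2[2] - p1[2], p2[1] - p1[1]) * 180 / pi)
  height <- (max(pts[, 3]) - min(pts[, 3]))
  pc <- stats::prcomp(pts[, 1:2])
  low_aniso <- pc$sdev[1] < 1.2 * pc$sdev[2]
  list(angle = angle, height = height, major_len = mp$distance,
       low_anisotropy = low_aniso, threshold = threshold)
}
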