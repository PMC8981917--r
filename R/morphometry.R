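#' Specimen geometry record
#'
#' Paired top-view widths and side-view heights measured at sampled
#' positions around the ring; per-position elliptical areas give the
#' minimum and mean initial cross-sections used for stress.
#'
#' @param widths mm, positive.
#' @param heights mm, positive; a single value is broadcast (width and
#'   height assumed co-located otherwise).
#' @param ring_diameter Nominal ring (peg) diameter, mm (default 5).
#' @return Object of class `specimen_geometry` with `a0_min`, `a0_mean`.
#' @export
specimen_geometry <- function(widths, heights, ring_diameter = 5) {
  if (length(heights) == 1L) heights <- rep(heights, length(widths))
  av <- area_variants(widths, heights)
  structure(list(widths = as.numeric(widths), heights = as.numeric(heights),
                 a0_min = av[["a0_min"]], a0_mean = av[["a0_mean"]],
                 ring_diameter = ring_diameter),
            class = "specimen_geometry")
}

#' Read geometry from YAML
#'
#' Keys: `widths_mm`, `heights_mm`, optional `ring_diameter_mm`.
#' @param path YAML file path.
#' @return A [specimen_geometry()].
#' @export
read_geometry <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$widths_mm) || is.null(x$heights_mm))
    stop("geometry YAML must contain widths_mm and heights_mm")
  specimen_geometry(unlist(x$widths_mm), unlist(x$heights_mm),
                    ring_diameter = if (is.null(x$ring_diameter_mm)) 5
                                    else x$ring_diameter_mm)
}

#' Minimum and mean elliptical cross-sections
#'
#' @param widths,heights Equal-length positive mm arrays (a scalar
#'   height is broadcast).
#' @return Named vector `c(a0_min = , a0_mean = )` in mm^2.
#' @export
area_variants <- function(widths, heights) {
  if (length(heights) == 1L) heights <- rep(heights, length(widths))
  if (length(widths) != length(heights))
    stop("widths and heights must have equal length")
  a <- elliptical_area(widths, heights)
  c(a0_min = min(a), a0_mean = mean(a))
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric, length >= 2, positive mean.
#' @return Dimensionless CV.
#' @examples
#' coefficient_of_variation(c(100, 100, 200, 200))  # 0.3849
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  stats::sd(values) / m
}

#' Segment the ring in a grayscale image
#'
#' Global Otsu threshold, connected-component labelling, removal of
#' small speckles, and selection of the single remaining large
#' component.  The reported centre is the centroid of the enclosed
#' lumen (the rings are cast around a circular peg, so the hole centre
#' is unbiased even when the ring wall is asymmetrically thick; the
#' mask centroid would shift towards the thick side).  If the
#' component encloses no hole the mask centroid is used.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param min_area_frac Components smaller than this fraction of the
#'   largest are discarded as speckles (default 0.05).
#' @return List with `mask` (logical matrix), `center` (row, col in
#'   pixel coordinates) and `mask_centroid`.
#' @export
segment_ring <- function(img, min_area_frac = 0.05) {
  if (!is.matrix(img)) stop("img must be a numeric matrix")
  rng <- range(img)
  if (diff(rng) < 1e-6) stop("segmentation error: blank image")
  th <- EBImage::otsu(EBImage::Image(img), range = rng)
  mask0 <- img > th
  if (!any(mask0)) stop("segmentation error: no foreground after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(mask0))
  areas <- tabulate(as.integer(EBImage::imageData(lab)))
  big <- which(areas >= min_area_frac * max(areas))
  if (length(big) == 0) stop("segmentation error: no component found")
  if (length(big) > 1)
    stop(sprintf("segmentation error: %d plausible components after filtering",
                 length(big)))
  mask <- matrix(EBImage::imageData(lab) == big, nrow(img), ncol(img))
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))) > 0
  hole <- filled & !mask
  if (any(hole)) {
    hidx <- which(hole, arr.ind = TRUE)
    center <- c(mean(hidx[, 1]), mean(hidx[, 2]))
  } else {
    center <- centroid
  }
  list(mask = mask, center = center, mask_centroid = centroid)
}

#' Radial thickness profile of a ring mask
#'
#' Casts `n_angles` rays from the centre; at each angle the thickness
#' is the radial extent of the foreground crossing (outer minus inner
#' boundary radius) scaled by the pixel size.  Boundaries are located
#' to sub-pixel precision: the binary mask is sampled bilinearly along
#' the ray and each boundary is the interpolated 0.5-level crossing,
#' which removes most of the half-pixel quantization a nearest-pixel
#' lookup would leave in the profile (and hence in its CV).  Rays with
#' no foreground crossing are recorded missing; more than 10 % missing
#' is an error (e.g. centre outside the ring).
#'
#' @param mask Logical matrix from [segment_ring()].
#' @param center Ring centre (row, col) in pixels.
#' @param n_angles Number of rays (default 360).
#' @param pixel_size Physical size of one pixel, um/px (default 1).
#' @param radial_step Ray sampling step in pixels (default 0.25).
#' @return Object of class `thickness_profile`: `angles` (radians),
#'   `thickness` (um, NA where missing), `mean`, `sd`, `cv`.
#' @export
thickness_profile <- function(mask, center, n_angles = 360L, pixel_size = 1,
                              radial_step = 0.25) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  nr <- nrow(mask); nc <- ncol(mask)
  if (center[1] < 1 || center[1] > nr || center[2] < 1 || center[2] > nc)
    stop("center outside the image")
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  rmax <- sqrt(nr^2 + nc^2) / 2
  radii <- seq(radial_step, rmax, by = radial_step)
  m <- matrix(as.numeric(mask), nr, nc)
  bilinear <- function(xs, ys) {
    x0 <- pmin(pmax(floor(xs), 1L), nr - 1L)
    y0 <- pmin(pmax(floor(ys), 1L), nc - 1L)
    fx <- xs - x0; fy <- ys - y0
    m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
      m[cbind(x0 + 1L, y0)] * fx * (1 - fy) +
      m[cbind(x0, y0 + 1L)] * (1 - fx) * fy +
      m[cbind(x0 + 1L, y0 + 1L)] * fx * fy
  }
  thick <- rep(NA_real_, n_angles)
  for (k in seq_len(n_angles)) {
    xs <- center[1] + radii * cos(angles[k])
    ys <- center[2] + radii * sin(angles[k])
    ok <- xs >= 1 & xs <= nr & ys >= 1 & ys <= nc
    if (!any(ok)) next
    vals <- bilinear(xs[ok], ys[ok])
    rr <- radii[ok]
    idx <- which(vals >= 0.5)
    if (length(idx) == 0) next
    k1 <- idx[1]; k2 <- idx[length(idx)]
    r_in <- if (k1 == 1L) rr[1] else
      rr[k1 - 1L] + radial_step * (0.5 - vals[k1 - 1L]) / (vals[k1] - vals[k1 - 1L])
    r_out <- if (k2 == length(rr)) rr[k2] else
      rr[k2] + radial_step * (vals[k2] - 0.5) / (vals[k2] - vals[k2 + 1L])
    thick[k] <- (r_out - r_in) * pixel_size
  }
  n_missing <- sum(is.na(thick))
  if (n_missing > 0.1 * n_angles)
    stop(sprintf("thickness profile failed: %d of %d rays found no ring crossing",
                 n_missing, n_angles))
  v <- thick[!is.na(thick)]
  structure(list(angles = angles, thickness = thick,
                 mean = mean(v), sd = stats::sd(v),
                 cv = stats::sd(v) / mean(v),
                 n_missing = n_missing, pixel_size = pixel_size),
            class = "thickness_profile")
}

#' Full ring morphometry from an image
#'
#' Convenience wrapper: [segment_ring()] then [thickness_profile()].
#'
#' @inheritParams segment_ring
#' @inheritParams thickness_profile
#' @return A `thickness_profile` with the segmentation `center` attached.
#' @export
measure_ring <- function(img, n_angles = 360L, pixel_size = 1,
                         min_area_frac = 0.05) {
  seg <- segment_ring(img, min_area_frac)
  prof <- thickness_profile(seg$mask, seg$center, n_angles, pixel_size)
  prof$center <- seg$center
  prof
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf("Ring thickness profile: %d rays (%d missing)\n",
              length(x$angles), x$n_missing))
  cat(sprintf("  mean %.2f, sd %.2f (um at %.2f um/px), CV %.4f\n",
              x$mean, x$sd, x$pixel_size, x$cv))
  invisible(x)
}
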