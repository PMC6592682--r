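#' Maximum-intensity projection
#'
#' Pixelwise maximum across the planes of a z- or t-stack, the standard
#' flattening applied to confocal stacks before ROI quantitation.
#'
#' @param stack a [frame_stack()], an H x W x n array, or a list of
#'   matrices.
#' @return a single H x W matrix.
#' @export
max_intensity_projection <- function(stack) {
  if (inherits(stack, "frame_stack")) stack <- stack$frames
  if (is.list(stack)) stack <- simplify2array(stack)
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (dim(stack)[3] == 0) stop("empty stack")
  apply(stack, c(1, 2), max)
}

#' Polygonal region of interest
#'
#' A simple (non-self-intersecting) polygon in 0-based pixel coordinates.
#' A pixel belongs to the ROI iff its center lies inside the polygon by
#' the even-odd rule.
#'
#' @param vertices n x 2 matrix of `(x, y)` vertices in px.
#' @return a `roi` object.
#' @export
roi_polygon <- function(vertices) {
  vertices <- matrix(as.numeric(vertices), ncol = 2L)
  if (nrow(vertices) < 3) stop("a polygon needs at least three vertices")
  structure(list(vertices = vertices), class = "roi")
}

#' Rasterize an ROI to a logical mask
#'
#' @param roi an [roi_polygon()] or an existing logical/numeric mask
#'   matrix.
#' @param dim image dimensions `c(height, width)` (required for polygons).
#' @return logical matrix of pixel membership.
#' @export
rasterize_roi <- function(roi, dim = NULL) {
  if (is.matrix(roi)) return(roi > 0)
  stopifnot(inherits(roi, "roi"), !is.null(dim))
  H <- dim[1]; W <- dim[2]
  px <- as.vector(col(matrix(0, H, W))) - 1  # x = column, 0-based centers
  py <- as.vector(row(matrix(0, H, W))) - 1
  matrix(point_in_polygon(px, py, roi$vertices), H, W)
}

# even-odd (crossing number) point-in-polygon test, vectorized over points
point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Background-corrected mean fluorescence of an ROI
#'
#' Implements the standard ImageJ-style quantitation: the ROI's integrated
#' intensity minus the pooled background mean times the ROI area, divided
#' by the ROI area — i.e. corrected mean intensity per unit area.
#' Background ROIs are pooled pixelwise.  Negative corrected values are
#' retained (with a message), not clipped.
#'
#' @param image intensity matrix.
#' @param roi the ROI (polygon or mask).
#' @param background_rois list of one or more background ROIs, disjoint
#'   from `roi`.
#' @return an `intensity_measurement`: `roi_integrated`, `roi_area` (px^2),
#'   `background_mean`, `corrected_per_area`.
#' @export
corrected_mean_intensity <- function(image, roi, background_rois) {
  stopifnot(is.matrix(image))
  if (inherits(background_rois, "roi") || is.matrix(background_rois))
    background_rois <- list(background_rois)
  if (!length(background_rois))
    stop("at least one background ROI is required")
  m <- rasterize_roi(roi, dim(image))
  if (!any(m)) stop("ROI covers no pixels")
  bg <- Reduce(`|`, lapply(background_rois, rasterize_roi, dim = dim(image)))
  if (any(m & bg)) stop("background ROIs overlap the measurement ROI")
  if (!any(bg)) stop("background ROIs cover no pixels")
  roi_integrated <- sum(image[m])
  roi_area <- sum(m)
  background_mean <- mean(image[bg])
  corrected <- (roi_integrated - background_mean * roi_area) / roi_area
  if (corrected < 0)
    message("corrected intensity is negative (ROI dimmer than background)")
  structure(list(roi_integrated = roi_integrated, roi_area = roi_area,
                 background_mean = background_mean,
                 corrected_per_area = corrected),
            class = "intensity_measurement")
}

#' Fold increase of corrected fluorescence over a control pool
#'
#' @param measurement an `intensity_measurement` (or its
#'   `corrected_per_area` value).
#' @param control_measurements list of control `intensity_measurement`s
#'   (or a numeric vector of corrected values) with positive mean.
#' @return dimensionless fold increase.
#' @export
fold_increase <- function(measurement, control_measurements) {
  val <- if (inherits(measurement, "intensity_measurement"))
    measurement$corrected_per_area else as.numeric(measurement)
  ctrl <- vapply(control_measurements, function(x) {
    if (inherits(x, "intensity_measurement")) x$corrected_per_area
    else as.numeric(x)
  }, numeric(1))
  if (!length(ctrl) || mean(ctrl) <= 0)
    stop("control corrected intensities must have a positive mean")
  val / mean(ctrl)
}

#' Fractional area change
#'
#' `FAC = (EDA - ESA) / EDA * 100`, the 2-D contractility index computed
#' from end-diastolic and end-systolic chamber areas.
#'
#' @param eda end-diastolic area (px^2 or any consistent unit, > 0).
#' @param esa end-systolic area (same unit).
#' @return FAC in percent; negative values are permitted with a warning.
#' @export
fractional_area_change <- function(eda, esa) {
  if (!is.finite(eda) || eda <= 0) stop("end-diastolic area must be > 0")
  fac <- (eda - esa) / eda * 100
  if (fac < 0)
    warning("negative FAC: end-systolic area exceeds end-diastolic area")
  fac
}

#' Labeled-area coverage of a region
#'
#' Percentage of the region covered by the labeled mask:
#' `area(labeled & region) / area(region) * 100`.
#'
#' @param labeled_mask,region_mask logical/numeric masks or
#'   [roi_polygon()]s of equal extent.
#' @param dim image dimensions, required when both inputs are polygons.
#' @return coverage in percent, in `[0, 100]`.
#' @export
area_coverage <- function(labeled_mask, region_mask, dim = NULL) {
  if (is.null(dim)) {
    if (is.matrix(labeled_mask)) dim <- dim(labeled_mask)
    else if (is.matrix(region_mask)) dim <- dim(region_mask)
  }
  lab <- rasterize_roi(labeled_mask, dim)
  reg <- rasterize_roi(region_mask, dim)
  stopifnot(all(dim(lab) == dim(reg)))
  if (!any(reg)) stop("region mask is empty")
  sum(lab & reg) / sum(reg) * 100
}

#' Ventricular area normalized to a control pool
#'
#' @param ventricle area of the ventricle mask (px^2), or a mask whose
#'   `TRUE` pixels are counted.
#' @param control_areas numeric vector of control ventricular areas with
#'   positive mean.
#' @return dimensionless normalized area.
#' @export
normalized_ventricular_area <- function(ventricle, control_areas) {
  area <- if (is.matrix(ventricle)) sum(ventricle > 0)
          else as.numeric(ventricle)
  if (!length(control_areas)) stop("control area list is empty")
  cm <- mean(as.numeric(control_areas))
  if (!is.finite(cm) || cm <= 0) stop("control areas must have positive mean")
  area / cm
}
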