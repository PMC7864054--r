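#' Segmentation and cell-filter parameters
#'
#' Bundles the tunable parameters of the mCherry-based segmentation and of the
#' cell quality filters. Geometric filter bounds are the assay defaults: cells
#' outside 108--5400 um^2, longer than 32.4 um along the major axis, with a
#' pixel-unit area/perimeter ratio outside 25--300, or touching the image edge
#' are excluded from analysis.
#'
#' @param area_min,area_max Cell area bounds (um^2).
#' @param major_axis_max Maximum major-axis length (um).
#' @param area_over_perimeter_min,area_over_perimeter_max Bounds on the
#'   area/perimeter ratio, both measured in pixels.
#' @param band_width Width of the membrane-proximal band (um). The default,
#'   1.08 um, corresponds to 10 px at 0.108 um/px (x60 path) and 5 px at
#'   0.216 um/px (x20 path).
#' @param min_object_px Minimum object size (px) kept by the area opening.
#' @param open_radius,close_radius,dilate_radius Disc radii (px) for the
#'   morphological opening, closing and dilation applied after thresholding.
#' @param background_close_radius Disc radius (px) of the large structuring
#'   element used when carving out the background region.
#' @param h_minima Depth (px, in distance-transform units) of the h-minima
#'   suppression that seeds the watershed; larger values merge shallow basins
#'   and avoid oversegmentation.
#' @param threshold `"otsu"` (global; membrane-proximity protocol) or
#'   `"adaptive"` (local mean; channel-function protocol).
#' @param adaptive_halfwidth Half-width (px) of the local-mean window used when
#'   `threshold = "adaptive"`.
#' @param adaptive_offset Offset above the local mean (fraction of the
#'   intensity range) a pixel must exceed to be foreground.
#'
#' @return A list of class `seg_params`.
#' @export
#' @examples
#' p <- seg_params(band_width = 1.08)
#' p$area_min
seg_params <- function(area_min = 108, area_max = 5400,
                       major_axis_max = 32.4,
                       area_over_perimeter_min = 25,
                       area_over_perimeter_max = 300,
                       band_width = 1.08,
                       min_object_px = 50,
                       open_radius = 3, close_radius = 3, dilate_radius = 1,
                       background_close_radius = 15,
                       h_minima = 2,
                       threshold = c("otsu", "adaptive"),
                       adaptive_halfwidth = 15,
                       adaptive_offset = 0.01) {
  threshold <- match.arg(threshold)
  if (area_min >= area_max) stop("`area_min` must be < `area_max`")
  stopifnot_scalar_pos(band_width, "band_width")
  for (r in c(open_radius, close_radius, dilate_radius,
              background_close_radius)) {
    if (r < 1) stop("structuring-element radii must be >= 1 px")
  }
  structure(list(
    area_min = area_min, area_max = area_max,
    major_axis_max = major_axis_max,
    area_over_perimeter_min = area_over_perimeter_min,
    area_over_perimeter_max = area_over_perimeter_max,
    band_width = band_width, min_object_px = min_object_px,
    open_radius = open_radius, close_radius = close_radius,
    dilate_radius = dilate_radius,
    background_close_radius = background_close_radius,
    h_minima = h_minima, threshold = threshold,
    adaptive_halfwidth = adaptive_halfwidth,
    adaptive_offset = adaptive_offset
  ), class = "seg_params")
}

#' Binarize an mCherry image into a cell foreground mask
#'
#' Thresholds the mCherry channel and cleans the result with morphological
#' opening, closing, area opening (removal of objects below
#' `params$min_object_px`) and dilation, in that order.
#'
#' @param image Numeric matrix (or EBImage `Image`) of mCherry intensities.
#' @param params A [seg_params()] object.
#' @return Logical matrix: `TRUE` for foreground (cell) pixels. A constant
#'   image yields an all-`FALSE` mask with a `"no-foreground"` warning.
#' @export
binarize_mcherry <- function(image, params = seg_params()) {
  img <- as_intensity_matrix(image)
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("no-foreground: image is constant; returning empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  img01 <- (img - rng[1]) / diff(rng)
  if (params$threshold == "otsu") {
    # threshold on log intensities: fluorescence is long-tailed across cells,
    # and raw-scale Otsu can land inside the cell-intensity range
    lg <- log1p(img - rng[1])
    lg01 <- lg / max(lg)
    thr <- EBImage::otsu(EBImage::Image(lg01), range = c(0, 1), levels = 256)
    mask <- lg01 > thr
  } else {
    w <- params$adaptive_halfwidth
    mask <- EBImage::thresh(EBImage::Image(img01), w = w, h = w,
                            offset = params$adaptive_offset) > 0
  }
  mask <- EBImage::imageData(EBImage::opening(mask, disc_brush(params$open_radius)))
  mask <- EBImage::imageData(EBImage::closing(mask, disc_brush(params$close_radius)))
  # area opening: drop connected components smaller than min_object_px
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- sizes >= params$min_object_px
    mask <- array(lab > 0 & keep[pmax(lab, 1L)], dim = dim(lab))
  }
  mask <- EBImage::imageData(EBImage::dilate(mask, disc_brush(params$dilate_radius)))
  matrix(as.logical(mask > 0), nrow(img), ncol(img))
}

#' Split a foreground mask into individual cells by watershed
#'
#' Applies a watershed transform to the Euclidean distance map of the mask.
#' Shallow basins are merged through the `h_minima` tolerance so that each
#' isolated object yields one label while touching cells are separated along
#' distance-transform ridge lines.
#'
#' @param mask Logical matrix from [binarize_mcherry()].
#' @param params A [seg_params()] object.
#' @return Integer matrix of cell labels (1..K); 0 marks non-cell pixels.
#' @export
watershed_cells <- function(mask, params = seg_params()) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) {
    out <- matrix(0L, nrow(mask), ncol(mask))
    return(out)
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::watershed(dm, tolerance = params$h_minima, ext = 1)
  relabel_consecutive(EBImage::imageData(lab))
}

# Labels whose masks include a pixel on the image border.
edge_labels <- function(labels) {
  border <- c(labels[1, ], labels[nrow(labels), ],
              labels[, 1], labels[, ncol(labels)])
  sort(unique(border[border > 0]))
}

#' Apply geometric quality filters to segmented cells
#'
#' Computes per-cell geometry (area, perimeter, major axis) and flags cells
#' violating any filter: area outside `[area_min, area_max]` um^2, major axis
#' above `major_axis_max` um, pixel-unit area/perimeter outside
#' `[area_over_perimeter_min, area_over_perimeter_max]`, or touching the image
#' edge. Every label is either retained or logged with exactly one exclusion
#' reason (the first violated rule, in the order above).
#'
#' @param labels Integer label matrix from [watershed_cells()].
#' @param pixel_size Pixel size (um/px).
#' @param params A [seg_params()] object.
#' @return A `data.frame` with one row per label: `label`, `area_px`,
#'   `perimeter_px`, `area_um2`, `major_axis_um`, `area_over_perimeter`,
#'   `touches_edge`, `excluded`, `exclusion_reason`.
#' @export
filter_cells <- function(labels, pixel_size, params = seg_params()) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  n <- max(labels)
  if (n == 0L) {
    return(data.frame(label = integer(), area_px = numeric(),
                      perimeter_px = numeric(), area_um2 = numeric(),
                      major_axis_um = numeric(), area_over_perimeter = numeric(),
                      touches_edge = logical(), excluded = logical(),
                      exclusion_reason = character(),
                      stringsAsFactors = FALSE))
  }
  img <- EBImage::Image(labels)
  shp <- EBImage::computeFeatures.shape(img)
  mom <- EBImage::computeFeatures.moment(img)
  area_px <- shp[, "s.area"]
  perim_px <- shp[, "s.perimeter"]
  major_um <- mom[, "m.majoraxis"] * pixel_size
  area_um2 <- area_px * pixel_size^2
  aop <- area_px / perim_px
  edge <- seq_len(n) %in% edge_labels(labels)

  reason <- rep(NA_character_, n)
  reason[is.na(reason) & (area_um2 < params$area_min |
                          area_um2 > params$area_max)] <- "area"
  reason[is.na(reason) & major_um > params$major_axis_max] <- "major-axis"
  reason[is.na(reason) & (aop < params$area_over_perimeter_min |
                          aop > params$area_over_perimeter_max)] <- "area-perimeter"
  reason[is.na(reason) & edge] <- "edge"

  data.frame(label = seq_len(n), area_px = as.numeric(area_px),
             perimeter_px = as.numeric(perim_px),
             area_um2 = as.numeric(area_um2),
             major_axis_um = as.numeric(major_um),
             area_over_perimeter = as.numeric(aop),
             touches_edge = edge, excluded = !is.na(reason),
             exclusion_reason = reason, stringsAsFactors = FALSE)
}

#' Estimate the scalar image background
#'
#' The background region is the complement of the cell mask after closing the
#' mask with a large structuring element, which removes thin slivers between
#' adjacent cells from the background so that cell-adjacent pixels are not
#' selected as background. The returned value is the mean intensity over that
#' region; subtracting it from every pixel is the caller's contract.
#'
#' @param image Numeric intensity matrix (either channel).
#' @param mask Logical cell mask from [binarize_mcherry()].
#' @param params A [seg_params()] object (`background_close_radius` is used).
#' @return Scalar mean background intensity.
#' @export
estimate_background <- function(image, mask, params = seg_params()) {
  img <- as_intensity_matrix(image)
  if (!is.logical(mask)) mask <- mask > 0
  closed <- EBImage::imageData(
    EBImage::closing(mask, disc_brush(params$background_close_radius))) > 0
  bg <- !closed
  if (!any(bg)) stop("no-background-region: image is entirely foreground")
  mean(img[bg])
}
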