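#' Extract the membrane-proximal band of a cell mask
#'
#' The band comprises the mask pixels whose Euclidean distance to the cell
#' exterior is at most `round(band_width / pixel_size)` pixels, i.e. the 0 to
#' `band_px`-pixel zone inside the cell border. For cells thinner than twice
#' the band the band is the whole mask.
#'
#' @param mask Logical matrix for a single cell (non-empty).
#' @param pixel_size Pixel size (um/px).
#' @param band_width Band width (um); default 1.08 um (10 px at 0.108 um/px).
#' @return Logical matrix of the same dimensions: band pixels. Always a subset
#'   of `mask`.
#' @export
#' @examples
#' m <- matrix(FALSE, 30, 30); m[6:25, 6:25] <- TRUE
#' sum(membrane_band(m, pixel_size = 1, band_width = 5))  # 20^2 - 10^2 = 300
membrane_band <- function(mask, pixel_size, band_width = 1.08) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  stopifnot_scalar_pos(band_width, "band_width")
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop("`mask` is empty")
  band_px <- round(band_width / pixel_size)
  if (band_px < 1) {
    stop("band-too-thin: band width is < 1 px at this pixel size")
  }
  # pad with one background ring so the image edge counts as exterior
  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(padded)))
  dm <- dm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  band <- mask & dm <= band_px
  band
}

# Bounding box (row/col ranges) of a label in a label matrix.
label_bbox <- function(labels, l) {
  idx <- which(labels == l)
  rows <- ((idx - 1L) %% nrow(labels)) + 1L
  cols <- ((idx - 1L) %/% nrow(labels)) + 1L
  list(r = range(rows), c = range(cols))
}

#' Measure per-cell background-subtracted intensities
#'
#' For each retained cell, computes the mean background-subtracted mCherry and
#' YFP intensity over the whole mask and the mean background-subtracted YFP
#' intensity over the membrane-proximal band.
#'
#' @param pair List with numeric matrices `mcherry` and `yfp` (same shape).
#' @param labels Label matrix from [watershed_cells()].
#' @param cells Filter table from [filter_cells()].
#' @param background Named numeric vector `c(mcherry = , yfp = )` of scalar
#'   background levels (see [estimate_background()]).
#' @param pixel_size Pixel size (um/px).
#' @param band_width Membrane band width (um).
#' @return `cells` with columns `f_mcherry_cell_raw`, `f_yfp_cell_raw`,
#'   `f_yfp_membrane_raw`, `band_px_n` added (NA for excluded cells).
#' @export
measure_cells <- function(pair, labels, cells, background, pixel_size,
                          band_width = 1.08) {
  mch <- as_intensity_matrix(pair$mcherry, "mcherry") - background[["mcherry"]]
  yfp <- as_intensity_matrix(pair$yfp, "yfp") - background[["yfp"]]
  if (!all(dim(mch) == dim(yfp))) stop("channel dimensions differ")
  cells$f_mcherry_cell_raw <- NA_real_
  cells$f_yfp_cell_raw <- NA_real_
  cells$f_yfp_membrane_raw <- NA_real_
  cells$band_px_n <- NA_integer_
  inside <- labels > 0
  if (!any(inside)) return(cells)
  lab_v <- labels[inside]
  sums_m <- rowsum(mch[inside], lab_v)
  sums_y <- rowsum(yfp[inside], lab_v)
  counts <- tabulate(lab_v, nbins = max(labels))
  present <- as.integer(rownames(sums_m))
  mean_m <- setNames(sums_m[, 1] / counts[present], present)
  mean_y <- setNames(sums_y[, 1] / counts[present], present)
  for (i in which(!cells$excluded)) {
    l <- cells$label[i]
    key <- as.character(l)
    if (!key %in% names(mean_m)) next
    cells$f_mcherry_cell_raw[i] <- mean_m[[key]]
    cells$f_yfp_cell_raw[i] <- mean_y[[key]]
    bb <- label_bbox(labels, l)
    sub <- labels[bb$r[1]:bb$r[2], bb$c[1]:bb$c[2], drop = FALSE] == l
    band <- membrane_band(sub, pixel_size, band_width)
    ysub <- yfp[bb$r[1]:bb$r[2], bb$c[1]:bb$c[2], drop = FALSE]
    cells$f_yfp_membrane_raw[i] <- mean(ysub[band])
    cells$band_px_n[i] <- sum(band)
  }
  cells
}

#' Build the plate-level wild-type normalizer
#'
#' Collects the median background-subtracted YFP and mCherry whole-cell
#' intensities over all retained cells in wild-type reference wells of the
#' same plate. These medians are the denominators used by
#' [normalize_to_plate()].
#'
#' @param cells Per-cell table with raw intensity columns (from
#'   [measure_cells()]) and a logical `is_wt_reference` column.
#' @return List of class `plate_normalizer` with `wt_yfp_median`,
#'   `wt_mcherry_median` and `n_wt_cells`.
#' @export
plate_normalizer <- function(cells) {
  if (is.null(cells$is_wt_reference)) {
    stop("no-reference: `cells` lacks an `is_wt_reference` column")
  }
  wt <- cells[cells$is_wt_reference & !cells$excluded &
                !is.na(cells$f_mcherry_cell_raw), , drop = FALSE]
  if (nrow(wt) == 0L) {
    stop("no-reference: no retained wild-type reference cells on this plate")
  }
  structure(list(
    wt_yfp_median = median(wt$f_yfp_cell_raw),
    wt_mcherry_median = median(wt$f_mcherry_cell_raw),
    n_wt_cells = nrow(wt)
  ), class = "plate_normalizer")
}

#' Normalize per-cell intensities to the plate wild-type medians
#'
#' Divides the background-subtracted YFP intensities (whole cell and membrane
#' band) by the wild-type YFP median and the mCherry intensity by the
#' wild-type mCherry median. Cells whose mean normalized intensity on either
#' channel falls below 0 (dim cells in high background) are excluded with
#' reason `"negative-intensity"`.
#'
#' @param cells Table from [measure_cells()].
#' @param normalizer A [plate_normalizer()] object.
#' @return `cells` with columns `f_mcherry_cell`, `f_yfp_cell`,
#'   `f_yfp_membrane` added and negative-intensity cells excluded.
#' @export
normalize_to_plate <- function(cells, normalizer) {
  if (!inherits(normalizer, "plate_normalizer")) {
    stop("`normalizer` must come from plate_normalizer()")
  }
  if (normalizer$wt_yfp_median <= 0 || normalizer$wt_mcherry_median <= 0) {
    stop("no-reference: wild-type medians must be positive")
  }
  cells$f_mcherry_cell <- cells$f_mcherry_cell_raw / normalizer$wt_mcherry_median
  cells$f_yfp_cell <- cells$f_yfp_cell_raw / normalizer$wt_yfp_median
  cells$f_yfp_membrane <- cells$f_yfp_membrane_raw / normalizer$wt_yfp_median
  neg <- !cells$excluded & !is.na(cells$f_mcherry_cell) &
    (cells$f_mcherry_cell < 0 | cells$f_yfp_cell < 0)
  cells$excluded[neg] <- TRUE
  cells$exclusion_reason[neg] <- "negative-intensity"
  cells
}

#' Compute the membrane-proximity metric rho per cell
#'
#' rho is the mean normalized YFP fluorescence in the membrane-proximal band
#' divided by the mean normalized mCherry fluorescence over the whole cell.
#' The two factor metrics are also exposed: `factor_membrane`
#' (band YFP / whole-cell YFP, the fraction of YFP-CFTR near the border) and
#' `factor_stability` (whole-cell YFP / whole-cell mCherry, the metabolic
#' stability of the fusion relative to the co-translated standard). Their
#' product equals rho.
#'
#' @param cells Normalized table from [normalize_to_plate()].
#' @return `cells` with `rho`, `factor_membrane`, `factor_stability` added;
#'   cells with non-positive mCherry reference excluded with reason
#'   `"non-positive-reference"`.
#' @export
compute_rho <- function(cells) {
  if (is.null(cells$f_mcherry_cell)) {
    stop("cells must be normalized first (see normalize_to_plate())")
  }
  bad <- !cells$excluded & !is.na(cells$f_mcherry_cell) &
    cells$f_mcherry_cell <= 0
  cells$excluded[bad] <- TRUE
  cells$exclusion_reason[bad] <- "non-positive-reference"
  ok <- !cells$excluded & !is.na(cells$f_mcherry_cell)
  cells$rho <- NA_real_
  cells$factor_membrane <- NA_real_
  cells$factor_stability <- NA_real_
  cells$rho[ok] <- cells$f_yfp_membrane[ok] / cells$f_mcherry_cell[ok]
  cells$factor_membrane[ok] <- cells$f_yfp_membrane[ok] / cells$f_yfp_cell[ok]
  cells$factor_stability[ok] <- cells$f_yfp_cell[ok] / cells$f_mcherry_cell[ok]
  cells
}

#' Log-transform rho and summarize per plate
#'
#' Adds the base-10 logarithm of rho per cell. rho distributions are skewed
#' and approximately log-normal, so statistics are computed on log10(rho).
#' Cells with rho <= 0 are excluded from log statistics with reason
#' `"non-positive-rho"`.
#'
#' @param cells Table from [compute_rho()].
#' @return `cells` with a `log10_rho` column.
#' @export
log_rho <- function(cells) {
  if (is.null(cells$rho)) stop("cells must carry `rho` (see compute_rho())")
  bad <- !cells$excluded & !is.na(cells$rho) & cells$rho <= 0
  cells$excluded[bad] <- TRUE
  cells$exclusion_reason[bad] <- "non-positive-rho"
  cells$log10_rho <- NA_real_
  ok <- !cells$excluded & !is.na(cells$rho) & cells$rho > 0
  cells$log10_rho[ok] <- log10(cells$rho[ok])
  cells
}

#' Summarize per-cell rho by plate/genotype/condition
#'
#' @param cells Table from [log_rho()] carrying grouping columns.
#' @param by Character vector of grouping columns present in `cells`.
#' @return `data.frame` with the grouping columns, `mean_log10_rho`,
#'   `mean_rho`, `mean_f_mcherry_cell` and `n_cells` per group (retained
#'   cells only).
#' @export
summarize_cells <- function(cells,
                            by = intersect(c("plate_id", "well", "genotype",
                                             "condition", "temperature"),
                                           names(cells))) {
  ok <- cells[!cells$excluded & !is.na(cells$log10_rho), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no retained cells to summarize")
  key <- interaction(ok[by], drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(ok)), key), function(i) {
    row <- ok[i[1], by, drop = FALSE]
    row$mean_log10_rho <- mean(ok$log10_rho[i])
    row$mean_rho <- mean(ok$rho[i])
    row$mean_f_mcherry_cell <- mean(ok$f_mcherry_cell[i])
    row$n_cells <- length(i)
    row
  }))
  rownames(agg) <- NULL
  agg
}

#' Segment and measure one imaging field
#'
#' Runs the full per-field imaging chain: binarize the mCherry channel,
#' estimate per-channel backgrounds, watershed-split into cells, apply the
#' geometric filters and measure raw (background-subtracted) intensities.
#' Plate-level normalization and rho are applied afterwards once wild-type
#' reference cells for the whole plate are available (see
#' [plate_normalizer()]).
#'
#' @param pair List with `mcherry` and `yfp` intensity matrices.
#' @param pixel_size Pixel size (um/px); must be supplied (never inferred).
#' @param params A [seg_params()] object.
#' @return List with `cells` (measured filter table), `labels` (label
#'   matrix) and `background` (named vector).
#' @export
analyze_field <- function(pair, pixel_size, params = seg_params()) {
  mask <- binarize_mcherry(pair$mcherry, params)
  labels <- watershed_cells(mask, params)
  bg <- c(mcherry = estimate_background(pair$mcherry, mask, params),
          yfp = estimate_background(pair$yfp, mask, params))
  cells <- filter_cells(labels, pixel_size, params)
  cells <- measure_cells(pair, labels, cells, bg, pixel_size,
                         band_width = params$band_width)
  list(cells = cells, labels = labels, background = bg)
}
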