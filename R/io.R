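#' Solute concentration after an ideal-mixing addition
#'
#' Concentration after adding `v_added` of a stock at `c_added` to a well
#' holding `v_well` at `c_well`, assuming ideal mixing:
#' `(c_well * v_well + c_added * v_added) / (v_well + v_added)`.
#' Units are preserved (use the same volume unit for both volumes and the
#' same concentration unit for both concentrations).
#'
#' @param c_well Concentration already in the well.
#' @param v_well Well volume before the addition (ul).
#' @param c_added Concentration of the added stock.
#' @param v_added Added volume (ul).
#' @return Final concentration, same unit as the inputs.
#' @export
#' @examples
#' final_concentration(0, 100, 300, 50)  # 100 mM iodide
#' final_concentration(0, 150, 40, 50)   # 10 uM forskolin
final_concentration <- function(c_well, v_well, c_added, v_added) {
  stopifnot_scalar_pos(v_well, "v_well")
  stopifnot_scalar_pos(v_added, "v_added")
  (c_well * v_well + c_added * v_added) / (v_well + v_added)
}

#' Read a two-channel image pair from TIFF files
#'
#' Reads 16-bit grayscale TIFFs (one file per channel), rescales to raw
#' counts, and checks that the channels share dimensions.
#'
#' @param mcherry_path,yfp_path Paths to the per-channel TIFF files.
#' @param pixel_size Pixel size (um/px), attached to the pair.
#' @return List with `mcherry`, `yfp` (numeric matrices) and `pixel_size`.
#' @export
read_image_pair <- function(mcherry_path, yfp_path, pixel_size) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  rd <- function(p) {
    if (!file.exists(p)) stop(sprintf("image file not found: %s", p))
    img <- tryCatch(tiff::readTIFF(p), error = function(e) {
      stop(sprintf("cannot read TIFF '%s': %s", p, conditionMessage(e)))
    })
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img * 65535
  }
  mch <- rd(mcherry_path); yfp <- rd(yfp_path)
  if (!all(dim(mch) == dim(yfp))) {
    stop(sprintf("channel shape mismatch: %s vs %s",
                 paste(dim(mch), collapse = "x"),
                 paste(dim(yfp), collapse = "x")))
  }
  list(mcherry = mch, yfp = yfp, pixel_size = pixel_size)
}

#' Write a synthetic plate bundle to disk
#'
#' Writes the formats the pipeline reads back: `platemap.csv`, 16-bit
#' per-channel TIFFs under `images/` (`<well>_mcherry.tif`, `<well>_yfp.tif`),
#' a long-format `traces.csv`, and the generator truth tables
#' (`truth_cells.csv`, `truth_traces.csv`).
#'
#' @param bundle A [make_plate()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$plate_map, file.path(dir, "platemap.csv"),
            row.names = FALSE)
  for (w in names(bundle$fields)) {
    pair <- bundle$fields[[w]]$pair
    tiff::writeTIFF(pmin(pair$mcherry / 65535, 1),
                    file.path(dir, "images", paste0(w, "_mcherry.tif")),
                    bits.per.sample = 16)
    tiff::writeTIFF(pmin(pair$yfp / 65535, 1),
                    file.path(dir, "images", paste0(w, "_yfp.tif")),
                    bits.per.sample = 16)
  }
  write.csv(bundle$truth_cells, file.path(dir, "truth_cells.csv"),
            row.names = FALSE)
  if (!is.null(bundle$traces)) {
    long <- do.call(rbind, lapply(names(bundle$traces$traces), function(w) {
      tr <- bundle$traces$traces[[w]]
      data.frame(well = w, time_s = tr$times, f_norm = tr$f_norm,
                 t_iodide = tr$t_iodide,
                 f_mcherry_well = tr$f_mcherry_well,
                 stringsAsFactors = FALSE)
    }))
    write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
    write.csv(bundle$traces$truth, file.path(dir, "truth_traces.csv"),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a plate bundle from disk
#'
#' Inverse of [write_plate_bundle()] for real or simulated data laid out as
#' `platemap.csv` + `images/<well>_<channel>.tif` (+ optional `traces.csv`).
#' Fails fast, naming any missing well image.
#'
#' @param dir Bundle directory.
#' @param pixel_size Pixel size of the imaging wells (um/px).
#' @return List with `plate_map`, `fields` (per imaging well: list with
#'   `pair`), `traces` (named list of `quench_trace` or `NULL`).
#' @export
read_plate_bundle <- function(dir, pixel_size = 0.108) {
  map_path <- file.path(dir, "platemap.csv")
  if (!file.exists(map_path)) stop("missing platemap.csv in ", dir)
  plate_map <- read.csv(map_path, stringsAsFactors = FALSE)
  img_wells <- plate_map$well[plate_map$role == "imaging"]
  missing <- img_wells[!vapply(img_wells, function(w) {
    file.exists(file.path(dir, "images", paste0(w, "_mcherry.tif"))) &&
      file.exists(file.path(dir, "images", paste0(w, "_yfp.tif")))
  }, logical(1))]
  if (length(missing) > 0L) {
    stop("missing channel images for wells: ", paste(missing, collapse = ", "))
  }
  fields <- lapply(setNames(img_wells, img_wells), function(w) {
    list(pair = read_image_pair(
      file.path(dir, "images", paste0(w, "_mcherry.tif")),
      file.path(dir, "images", paste0(w, "_yfp.tif")), pixel_size))
  })
  traces <- NULL
  tr_path <- file.path(dir, "traces.csv")
  if (file.exists(tr_path)) {
    long <- read.csv(tr_path, stringsAsFactors = FALSE)
    traces <- lapply(split(long, long$well), function(d) {
      d <- d[order(d$time_s), ]
      structure(list(times = d$time_s, f_norm = d$f_norm,
                     t_iodide = d$t_iodide[1], t_activation = NA_real_,
                     iodide_out = 100,
                     f_mcherry_well = d$f_mcherry_well[1]),
                class = "quench_trace")
    })
  }
  list(plate_map = plate_map, fields = fields, traces = traces)
}

#' Export result tables as schema-stamped CSV files
#'
#' Writes each table as UTF-8 CSV with a leading comment line recording the
#' package version and column schema, so outputs are self-describing and
#' round-trip with [read_results()].
#'
#' @param tables Named list of `data.frame`s.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_results <- function(tables, out_dir) {
  ok <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.access(out_dir, 2) == 0
  }, error = function(e) FALSE)
  if (!ok) stop("output directory is not writable: ", out_dir)
  ver <- as.character(utils::packageVersion("rhoquench"))
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# rhoquench %s | table: %s | columns: %s",
                       ver, nm, paste(names(tables[[nm]]), collapse = ",")),
               con)
    write.csv(tables[[nm]], con, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Read back a CSV written by [export_results()]
#'
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_results <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Segment, normalize and compute rho for all imaging wells of a plate
#'
#' Runs [analyze_field()] on each imaging well, pools the cells, builds the
#' wild-type plate normalizer, normalizes, computes rho and log10(rho), and
#' summarizes per well. The per-well mean normalized mCherry
#' (`f_mcherry_well`) is reported for expression normalization of the
#' function metrics.
#'
#' @param fields Named list (by well) of lists carrying `pair` (as from
#'   [make_plate()] or [read_plate_bundle()]).
#' @param plate_map Plate map `data.frame` (`well`, `genotype`, `role`,
#'   `is_wt_reference`, ...).
#' @param pixel_size Pixel size (um/px).
#' @param params A [seg_params()] object.
#' @param plate_id Plate identifier added to the tables.
#' @return List: `cells` (per-cell table incl. exclusion log), `wells`
#'   (per-well summary with `f_mcherry_well`), `normalizer`.
#' @export
analyze_plate <- function(fields, plate_map, pixel_size,
                          params = seg_params(), plate_id = "plate1") {
  img_map <- plate_map[plate_map$role == "imaging", , drop = FALSE]
  if (!any(img_map$is_wt_reference)) {
    stop("no-reference: plate map designates no wild-type reference well")
  }
  all_cells <- list()
  for (w in img_map$well) {
    if (is.null(fields[[w]])) stop("missing field for imaging well ", w)
    res <- analyze_field(fields[[w]]$pair, pixel_size, params)
    cells <- res$cells
    cells$plate_id <- plate_id
    cells$well <- w
    cells$genotype <- img_map$genotype[img_map$well == w]
    if ("condition" %in% names(img_map)) {
      cells$condition <- img_map$condition[img_map$well == w]
    }
    cells$is_wt_reference <- img_map$is_wt_reference[img_map$well == w]
    all_cells[[w]] <- cells
  }
  cells <- do.call(rbind, all_cells)
  rownames(cells) <- NULL
  normalizer <- plate_normalizer(cells)
  cells <- normalize_to_plate(cells, normalizer)
  cells <- compute_rho(cells)
  cells <- log_rho(cells)
  wells <- summarize_cells(cells, by = intersect(
    c("plate_id", "well", "genotype", "condition"), names(cells)))
  wells$f_mcherry_well <- wells$mean_f_mcherry_cell
  list(cells = cells, wells = wells, normalizer = normalizer)
}

#' Run the full dual-readout pipeline on a plate bundle
#'
#' End-to-end orchestration: segmentation + rho for the imaging wells,
#' quench-trace analysis for the trace wells (steady-state conductance fits,
#' or maximal entry rate for wells whose plate-map `protocol` is `"A"`), and
#' expression normalization. Deterministic given the inputs and the fit seed;
#' every excluded cell and every constrained fit is recorded in the outputs.
#'
#' @param bundle A [make_plate()] bundle or the result of
#'   [read_plate_bundle()].
#' @param out_dir Optional directory; when given, all tables are written via
#'   [export_results()].
#' @param pixel_size Pixel size of the imaging wells (um/px).
#' @param params A [seg_params()] object.
#' @param constants A [kinetics_constants()] object.
#' @param control_averages Optional `c(G_trans = , tau_trans = )` negative-
#'   control averages forwarded to [fit_quench()] for the constrained
#'   fallback.
#' @param fit_seed Seed for the fit restart jitter.
#' @return List of tables: `cells`, `wells`, `quench` (per trace well), plus
#'   `exclusions` (the per-cell exclusion log).
#' @export
run_pipeline <- function(bundle, out_dir = NULL, pixel_size = 0.108,
                         params = seg_params(),
                         constants = kinetics_constants(),
                         control_averages = NULL, fit_seed = 1) {
  plate_map <- bundle$plate_map
  plate_id <- if (!is.null(bundle$plate_id)) bundle$plate_id else "plate1"
  imaging <- analyze_plate(bundle$fields, plate_map, pixel_size, params,
                           plate_id = plate_id)
  quench <- NULL
  traces <- bundle$traces
  if (inherits(traces, "synthetic_traces")) traces <- traces$traces
  if (!is.null(traces) && length(traces) > 0L) {
    tr_map <- plate_map[plate_map$role == "trace", , drop = FALSE]
    rows <- lapply(names(traces), function(w) {
      tr <- traces[[w]]
      proto <- if ("protocol" %in% names(tr_map)) {
        tr_map$protocol[tr_map$well == w]
      } else "B"
      if (length(proto) == 0L) proto <- "B"
      fm <- tr$f_mcherry_well
      if (identical(proto, "A")) {
        er <- entry_rate(tr, constants)
        data.frame(plate_id = plate_id, well = w, protocol = "A",
                   max_rate_mM_per_s = er$max_rate,
                   rate_norm = normalize_rate(er$max_rate, fm),
                   G_CFTR_nS = NA_real_, V_M_mV = NA_real_,
                   G_trans_nS = NA_real_, tau_trans_s = NA_real_,
                   constrained = NA, rss = NA_real_, f_mcherry_well = fm,
                   G_CFTR_norm = NA_real_, stringsAsFactors = FALSE)
      } else {
        fit <- fit_quench(tr, constants, control_averages = control_averages,
                          seed = fit_seed)
        data.frame(plate_id = plate_id, well = w, protocol = "B",
                   max_rate_mM_per_s = NA_real_, rate_norm = NA_real_,
                   G_CFTR_nS = fit$params$G_CFTR, V_M_mV = fit$params$V_M,
                   G_trans_nS = fit$params$G_trans,
                   tau_trans_s = fit$params$tau_trans,
                   constrained = fit$constrained, rss = fit$rss,
                   f_mcherry_well = fm,
                   G_CFTR_norm = normalize_conductance(fit, fm),
                   stringsAsFactors = FALSE)
      }
    })
    quench <- do.call(rbind, rows)
    extra <- intersect(c("genotype", "condition"), names(tr_map))
    if (length(extra) > 0L) {
      quench <- merge(quench, tr_map[, c("well", extra), drop = FALSE],
                      by = "well", sort = FALSE)
    }
  }
  exclusions <- imaging$cells[imaging$cells$excluded,
                              c("plate_id", "well", "label",
                                "exclusion_reason"), drop = FALSE]
  out <- list(cells = imaging$cells, wells = imaging$wells,
              quench = quench, exclusions = exclusions)
  if (!is.null(out_dir)) {
    export_results(Filter(Negate(is.null), out), out_dir)
  }
  out
}
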