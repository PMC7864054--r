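#' Specification for a synthetic microscopy field
#'
#' Describes one simulated imaging field of irregular adherent cells: per-cell
#' cytosolic mCherry (lognormal intensity heterogeneity, matching the roughly
#' log-normal rho distributions seen in real fields), YFP with a configurable
#' membrane-band enrichment, uniform background and Gaussian read noise
#' (optional Poisson shot noise). Cells are elliptical, non-overlapping, and
#' placed on a jittered grid away from the image edge.
#'
#' @param n_cells Number of cells to place.
#' @param radius_um Range of semi-major axis lengths (um).
#' @param ellipticity Range of major/minor axis ratios (>= 1).
#' @param mcherry_meanlog,mcherry_sdlog Lognormal parameters of per-cell
#'   mCherry intensity (arbitrary 16-bit-range units).
#' @param yfp_ratio Mean interior YFP / mCherry ratio per cell.
#' @param yfp_ratio_sdlog Lognormal jitter (sdlog) on that ratio across cells.
#' @param enrichment Membrane enrichment e: ring YFP = e x interior YFP.
#' @param ring_width_um Width of the enriched ring (um).
#' @param background Uniform background level added to both channels.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param poisson Add Poisson shot noise on top of the signal.
#' @param pixel_size Pixel size (um/px); default the x60 path (0.108).
#' @param image_size `c(rows, cols)` in pixels.
#' @param gap_px Minimum gap between neighbouring cell envelopes (px).
#' @param seed RNG seed; a fixed seed makes the field byte-identical.
#' @return List of class `field_spec`.
#' @export
field_spec <- function(n_cells = 50, radius_um = c(7, 9),
                       ellipticity = c(1, 1.25),
                       mcherry_meanlog = log(1000), mcherry_sdlog = 0.35,
                       yfp_ratio = 1, yfp_ratio_sdlog = 0.1,
                       enrichment = 2, ring_width_um = 1.08,
                       background = 10, noise_sd = 5, poisson = FALSE,
                       pixel_size = 0.108, image_size = c(1700, 1700),
                       gap_px = 10, seed = NULL) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (any(radius_um <= 0) || any(ellipticity < 1)) {
    stop("radii must be positive and ellipticity >= 1")
  }
  structure(as.list(environment()), class = "field_spec")
}

# Paint one ellipse into logical form over a bounding-box grid.
ellipse_mask <- function(rows, cols, cx, cy, a, b, theta) {
  g <- expand.grid(r = rows, c = cols)
  dx <- g$c - cx; dy <- g$r - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  matrix((u / a)^2 + (v / b)^2 <= 1, nrow = length(rows))
}

#' Generate a ground-truthed synthetic imaging field
#'
#' Builds the mCherry/YFP image pair, the ground-truth label matrix and a
#' per-cell truth table. The truth table carries pixel-exact analytic values:
#' the ring mean is exactly `enrichment x interior` YFP, the whole-cell YFP
#' mean follows from the ring/interior pixel counts, and `rho_analytic` is
#' computed with the field's own cells as the normalization reference
#' (plate-level bundles recompute it against the designated wild-type wells).
#'
#' @param spec A [field_spec()].
#' @return List of class `synthetic_field`: `pair` (list `mcherry`, `yfp`),
#'   `labels` (truth label matrix), `truth` (`data.frame`), `spec`.
#' @export
make_field <- function(spec = field_spec()) {
  with_seed_if(spec$seed, {
    px <- spec$pixel_size
    nr <- spec$image_size[1]; nc <- spec$image_size[2]
    a_px_max <- max(spec$radius_um) / px
    edge_margin <- ceiling(a_px_max) + 5
    ncols <- ceiling(sqrt(spec$n_cells))
    nrows <- ceiling(spec$n_cells / ncols)
    pitch_r <- (nr - 2 * edge_margin) / nrows
    pitch_c <- (nc - 2 * edge_margin) / ncols
    if (min(pitch_r, pitch_c) < 2 * a_px_max + spec$gap_px) {
      stop("cannot place n_cells without overlap: image too small for the cell size")
    }
    slots <- expand.grid(i = seq_len(nrows), j = seq_len(ncols))
    slots <- slots[sample(nrow(slots), spec$n_cells), , drop = FALSE]

    a_um <- runif(spec$n_cells, spec$radius_um[1], spec$radius_um[2])
    ell <- runif(spec$n_cells, spec$ellipticity[1], spec$ellipticity[2])
    theta <- runif(spec$n_cells, 0, pi)
    mch_level <- rlnorm(spec$n_cells, spec$mcherry_meanlog, spec$mcherry_sdlog)
    ratio <- spec$yfp_ratio * rlnorm(spec$n_cells, 0, spec$yfp_ratio_sdlog)
    yfp_interior <- mch_level * ratio

    labels <- matrix(0L, nr, nc)
    mch_sig <- matrix(0, nr, nc)
    yfp_sig <- matrix(0, nr, nc)
    ring_px <- round(spec$ring_width_um / px)
    truth <- vector("list", spec$n_cells)

    for (k in seq_len(spec$n_cells)) {
      a <- a_um[k] / px
      b <- a / ell[k]
      jr <- pitch_r / 2 - a - spec$gap_px / 2
      jc <- pitch_c / 2 - a - spec$gap_px / 2
      cy <- edge_margin + (slots$i[k] - 0.5) * pitch_r + runif(1, -jr, jr)
      cx <- edge_margin + (slots$j[k] - 0.5) * pitch_c + runif(1, -jc, jc)
      rows <- max(1L, floor(cy - a)):min(nr, ceiling(cy + a))
      cols <- max(1L, floor(cx - a)):min(nc, ceiling(cx + a))
      m <- ellipse_mask(rows, cols, cx, cy, a, b, theta[k])
      # distance-to-exterior of this cell, same metric as the analysis band
      padded <- matrix(0, length(rows) + 2L, length(cols) + 2L)
      padded[2:(length(rows) + 1L), 2:(length(cols) + 1L)] <- m
      dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(padded)))
      dm <- dm[2:(length(rows) + 1L), 2:(length(cols) + 1L)]
      ring <- m & dm <= ring_px
      lab_sub <- labels[rows, cols]
      lab_sub[m] <- k
      labels[rows, cols] <- lab_sub
      mch_sub <- mch_sig[rows, cols]; mch_sub[m] <- mch_level[k]
      mch_sig[rows, cols] <- mch_sub
      yfp_sub <- yfp_sig[rows, cols]
      yfp_sub[m] <- yfp_interior[k]
      yfp_sub[ring] <- spec$enrichment * yfp_interior[k]
      yfp_sig[rows, cols] <- yfp_sub

      n_px <- sum(m); n_ring <- sum(ring)
      yfp_cell_mean <- yfp_interior[k] *
        (n_px - n_ring + spec$enrichment * n_ring) / n_px
      truth[[k]] <- data.frame(
        label = k, cx = cx, cy = cy, a_um = a_um[k], b_um = a_um[k] / ell[k],
        theta = theta[k], n_px = n_px, n_ring_px = n_ring,
        area_um2 = n_px * px^2, mch_level = mch_level[k],
        yfp_interior = yfp_interior[k],
        yfp_band_mean = spec$enrichment * yfp_interior[k],
        yfp_cell_mean = yfp_cell_mean, enrichment = spec$enrichment)
    }
    truth <- do.call(rbind, truth)
    # analytic rho with this field's cells as normalization reference
    med_y <- median(truth$yfp_cell_mean)
    med_m <- median(truth$mch_level)
    truth$rho_analytic <- (truth$yfp_band_mean / med_y) /
      (truth$mch_level / med_m)

    noisify <- function(sig) {
      img <- sig + spec$background
      if (spec$poisson) img <- img + (rpois_matrix(img) - img)
      img <- img + matrix(rnorm(length(img), 0, spec$noise_sd), nr, nc)
      pmax(img, 0)
    }
    pair <- list(mcherry = noisify(mch_sig), yfp = noisify(yfp_sig),
                 pixel_size = px)
    structure(list(pair = pair, labels = labels, truth = truth, spec = spec),
              class = "synthetic_field")
  })
}

rpois_matrix <- function(lambda) {
  matrix(stats::rpois(length(lambda), pmax(lambda, 0)), nrow(lambda))
}

#' Specification for synthetic quench traces
#'
#' @param params `data.frame` with one row per well: `well`, `G_CFTR`, `V_M`,
#'   `G_trans`, `tau_trans`, `f_mcherry_well`.
#' @param noise_sd Gaussian noise on the normalized fluorescence.
#' @param duration Post-iodide duration (s).
#' @param dt Sampling interval (s); acquisition at 0.5 Hz (2 s).
#' @param n_pre Pre-iodide samples (held at exactly 1; the last one is the
#'   normalization reference frame).
#' @param seed RNG seed.
#' @return List of class `trace_spec`.
#' @export
trace_spec <- function(params, noise_sd = 0.01, duration = 40, dt = 2,
                       n_pre = 3, seed = NULL) {
  need <- c("well", "G_CFTR", "V_M", "G_trans", "tau_trans", "f_mcherry_well")
  if (!all(need %in% names(params))) {
    stop("`params` must have columns: ", paste(need, collapse = ", "))
  }
  structure(list(params = params, noise_sd = noise_sd, duration = duration,
                 dt = dt, n_pre = n_pre, seed = seed), class = "trace_spec")
}

#' Generate synthetic quench traces with a truth table
#'
#' Simulates the forward model per well and adds i.i.d. Gaussian noise to the
#' post-iodide normalized fluorescence; pre-iodide samples sit at exactly 1
#' (the reference frame is noiseless by construction of the normalization).
#'
#' @param spec A [trace_spec()].
#' @param constants A [kinetics_constants()] object.
#' @return List of class `synthetic_traces`: `traces` (named list of
#'   `quench_trace`), `truth` (the generating parameter table).
#' @export
make_traces <- function(spec, constants = kinetics_constants()) {
  with_seed_if(spec$seed, {
    traces <- lapply(seq_len(nrow(spec$params)), function(i) {
      p <- spec$params[i, ]
      sim <- simulate_quench(
        quench_params(p$G_CFTR, p$V_M, p$G_trans, p$tau_trans),
        constants, duration = spec$duration, dt_sample = spec$dt)
      f_post <- sim$f_norm +
        rnorm(length(sim$f_norm), 0, spec$noise_sd) *
          c(0, rep(1, length(sim$f_norm) - 1L))  # t = 0 frame stays exact
      t_pre <- seq(-spec$n_pre * spec$dt, -spec$dt, by = spec$dt)
      structure(list(
        times = c(t_pre, sim$times), f_norm = c(rep(1, spec$n_pre), f_post),
        t_iodide = 0, t_activation = NA_real_,
        iodide_out = constants$iodide_out,
        f_mcherry_well = p$f_mcherry_well
      ), class = "quench_trace")
    })
    names(traces) <- spec$params$well
    structure(list(traces = traces, truth = spec$params, spec = spec),
              class = "synthetic_traces")
  })
}

#' Generate a full synthetic plate bundle
#'
#' Assembles an end-to-end fixture: one imaging field per imaging well (with
#' genotype-specific membrane enrichment) and one quench trace per trace
#' well, plus the plate map and all truth tables. At least one wild-type
#' reference imaging well is required, since plate normalization is undefined
#' without it. Analytic per-cell rho is recomputed against the wild-type
#' wells' cells.
#'
#' @param plate_map `data.frame` with columns `well`, `genotype`, `role`
#'   (`"imaging"` or `"trace"`), `is_wt_reference`, and optionally
#'   `condition`, `temperature`, `protocol`.
#' @param field_base A [field_spec()] used for every imaging well (enrichment
#'   and seed are overridden per well).
#' @param enrichment Named numeric vector: membrane enrichment per genotype.
#' @param trace_params Optional `data.frame` (as in [trace_spec()]) for the
#'   trace wells; rows are matched to trace wells by `well`.
#' @param noise_sd_trace Gaussian noise for the traces.
#' @param plate_id Plate identifier stored in the bundle.
#' @param seed Master seed; per-well seeds are derived from it.
#' @return List of class `synthetic_plate`: `plate_map`, `fields` (named by
#'   well), `traces` (`synthetic_traces` or `NULL`), `truth_cells`,
#'   `plate_id`.
#' @export
make_plate <- function(plate_map, field_base = field_spec(),
                       enrichment = c(WT = 2, F508del = 0.6),
                       trace_params = NULL, noise_sd_trace = 0.01,
                       plate_id = "plate1", seed = 1) {
  need <- c("well", "genotype", "role", "is_wt_reference")
  if (!all(need %in% names(plate_map))) {
    stop("`plate_map` must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(plate_map$well)) stop("wells must be unique")
  img_wells <- plate_map[plate_map$role == "imaging", , drop = FALSE]
  if (!any(img_wells$is_wt_reference)) {
    stop("no-reference: plate map has no wild-type reference imaging well")
  }
  fields <- list()
  truth_cells <- list()
  for (i in seq_len(nrow(img_wells))) {
    w <- img_wells$well[i]
    g <- img_wells$genotype[i]
    e <- enrichment[[g]]
    if (is.null(e)) stop(sprintf("no enrichment given for genotype '%s'", g))
    sp <- field_base
    sp$enrichment <- e
    sp$seed <- (seed * 1000L + i) %% .Machine$integer.max
    fld <- make_field(sp)
    fld$truth$well <- w
    fld$truth$genotype <- g
    fld$truth$is_wt_reference <- img_wells$is_wt_reference[i]
    fields[[w]] <- fld
    truth_cells[[w]] <- fld$truth
  }
  truth_cells <- do.call(rbind, truth_cells)
  # analytic rho against the plate's wild-type reference cells
  wt <- truth_cells[truth_cells$is_wt_reference, ]
  med_y <- median(wt$yfp_cell_mean)
  med_m <- median(wt$mch_level)
  truth_cells$rho_analytic <- (truth_cells$yfp_band_mean / med_y) /
    (truth_cells$mch_level / med_m)

  traces <- NULL
  trace_wells <- plate_map[plate_map$role == "trace", , drop = FALSE]
  if (nrow(trace_wells) > 0L) {
    if (is.null(trace_params)) stop("trace wells present but no `trace_params`")
    tp <- merge(trace_wells["well"], trace_params, by = "well", sort = FALSE)
    if (nrow(tp) != nrow(trace_wells)) {
      stop("every trace well needs a row in `trace_params`")
    }
    traces <- make_traces(trace_spec(tp, noise_sd = noise_sd_trace,
                                     seed = (seed * 1000L + 999L) %%
                                       .Machine$integer.max))
  }
  structure(list(plate_map = plate_map, fields = fields, traces = traces,
                 truth_cells = truth_cells, plate_id = plate_id, seed = seed),
            class = "synthetic_plate")
}

#' Match segmented cells to ground-truth cells by IoU
#'
#' Greedy one-to-one matching between two label matrices: for each truth
#' label, the candidate with the largest intersection-over-union is accepted
#' if the IoU exceeds the threshold and the candidate is still unclaimed.
#'
#' @param truth_labels,found_labels Integer label matrices of equal shape.
#' @param iou_min Minimum IoU for a match (default 0.7).
#' @return `data.frame`: `truth_label`, `found_label` (`NA` if unmatched),
#'   `iou`, `matched`.
#' @export
match_cells <- function(truth_labels, found_labels, iou_min = 0.7) {
  if (!all(dim(truth_labels) == dim(found_labels))) stop("shape mismatch")
  nt <- max(truth_labels); nf <- max(found_labels)
  at <- tabulate(truth_labels[truth_labels > 0], nbins = max(nt, 1))
  af <- tabulate(found_labels[found_labels > 0], nbins = max(nf, 1))
  both <- truth_labels > 0 & found_labels > 0
  inter <- table(truth = truth_labels[both], found = found_labels[both])
  used <- logical(nf)
  out <- data.frame(truth_label = seq_len(nt), found_label = NA_integer_,
                    iou = 0, matched = FALSE)
  for (t in seq_len(nt)) {
    key <- as.character(t)
    if (!key %in% rownames(inter)) next
    cand <- inter[key, ]
    cand_ids <- as.integer(colnames(inter))
    iou <- as.numeric(cand) / (at[t] + af[cand_ids] - as.numeric(cand))
    ord <- order(iou, decreasing = TRUE)
    for (j in ord) {
      if (iou[j] < iou_min) break
      if (!used[cand_ids[j]]) {
        used[cand_ids[j]] <- TRUE
        out$found_label[t] <- cand_ids[j]
        out$iou[t] <- iou[j]
        out$matched[t] <- TRUE
        break
      }
    }
  }
  out
}
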