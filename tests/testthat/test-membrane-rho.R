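test_that("membrane band has exact set arithmetic on a square cell", {
  m <- matrix(FALSE, 30, 30)
  m[6:25, 6:25] <- TRUE  # 20 x 20 square
  band <- membrane_band(m, pixel_size = 1, band_width = 5)
  expect_identical(sum(band), 300L)      # 20^2 - 10^2
  expect_true(all(m[band]))              # band subset of mask
  # interior 10 x 10 untouched
  expect_false(any(band[11:20, 11:20]))
})

test_that("band width conversion and limit cases behave as specified", {
  m <- matrix(FALSE, 40, 40)
  m[5:36, 5:36] <- TRUE
  # 1.08 um at 0.108 um/px is a 10-px band
  band <- membrane_band(m, pixel_size = 0.108, band_width = 1.08)
  inner <- m
  inner[15:26, 15:26] <- FALSE  # strip the 10-px rim: what remains is interior
  expect_false(any(band & inner & !m))  # sanity: band within mask
  expect_equal(sum(band), 32^2 - 12^2)

  # a cell thinner than twice the band is all band
  thin <- matrix(FALSE, 20, 40)
  thin[9:12, 5:35] <- TRUE
  expect_identical(membrane_band(thin, 1, 5), thin)

  expect_error(membrane_band(m, pixel_size = 3, band_width = 1.08),
               "band-too-thin")
  expect_error(membrane_band(matrix(FALSE, 5, 5), 1, 2), "empty")
})

test_that("band containment holds across a generated field", {
  fld <- make_field(small_field_spec(seed = 303))
  for (l in unique(fld$labels[fld$labels > 0])) {
    idx <- which(fld$labels == l, arr.ind = TRUE)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    sub <- fld$labels[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == l
    band <- membrane_band(sub, 0.108, 1.08)
    expect_true(all(sub[band]))
    expect_gt(sum(band), 0)
  }
})

make_measured_cells <- function() {
  # hand-built raw measurement table: 3 WT cells + 1 mutant + 1 negative
  data.frame(
    label = 1:5,
    excluded = FALSE, exclusion_reason = NA_character_,
    f_mcherry_cell_raw = c(100, 200, 300, 150, -3),
    f_yfp_cell_raw = c(110, 220, 330, 60, 5),
    f_yfp_membrane_raw = c(220, 440, 660, 30, 5),
    is_wt_reference = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("plate normalization divides by wild-type medians and drops negatives", {
  cells <- make_measured_cells()
  norm <- plate_normalizer(cells)
  expect_equal(norm$wt_mcherry_median, 200)
  expect_equal(norm$wt_yfp_median, 220)
  out <- normalize_to_plate(cells, norm)
  # hand-computed division oracle
  expect_equal(out$f_mcherry_cell, cells$f_mcherry_cell_raw / 200)
  expect_equal(out$f_yfp_membrane, cells$f_yfp_membrane_raw / 220)
  # cell 5 had negative mCherry mean -> removed with reason
  expect_true(out$excluded[5])
  expect_identical(out$exclusion_reason[5], "negative-intensity")
})

test_that("normalizing an already-normalized wild-type plate is idempotent", {
  cells <- make_measured_cells()[1:3, ]
  norm <- plate_normalizer(cells)
  once <- normalize_to_plate(cells, norm)
  # treat the normalized values as a new plate's raw values
  again <- once
  again$f_mcherry_cell_raw <- once$f_mcherry_cell
  again$f_yfp_cell_raw <- once$f_yfp_cell
  again$f_yfp_membrane_raw <- once$f_yfp_membrane
  norm2 <- plate_normalizer(again)
  expect_equal(norm2$wt_mcherry_median, 1)
  expect_equal(norm2$wt_yfp_median, 1)
  twice <- normalize_to_plate(again, norm2)
  expect_equal(twice$f_mcherry_cell, once$f_mcherry_cell)
  expect_equal(twice$f_yfp_membrane, once$f_yfp_membrane)
})

test_that("missing wild-type reference raises the no-reference error", {
  cells <- make_measured_cells()
  cells$is_wt_reference <- FALSE
  expect_error(plate_normalizer(cells), "no-reference")
  expect_error(plate_normalizer(cells[, setdiff(names(cells), "is_wt_reference")]),
               "no-reference")
})

test_that("rho is the band/reference ratio and the product of its factor metrics", {
  cells <- make_measured_cells()
  out <- compute_rho(normalize_to_plate(cells, plate_normalizer(cells)))
  # fixture cell: membrane 2.0, mCherry 1.0 in normalized units -> rho 2
  expect_equal(out$rho[2], (440 / 220) / (200 / 200))
  # identity: rho == factor_membrane * factor_stability to machine precision
  ok <- !out$excluded
  expect_equal(out$rho[ok],
               out$factor_membrane[ok] * out$factor_stability[ok],
               tolerance = 1e-12)
  # uniform cell with YFP == mCherry -> rho 1
  uni <- data.frame(label = 1L, excluded = FALSE,
                    exclusion_reason = NA_character_,
                    f_mcherry_cell_raw = 500, f_yfp_cell_raw = 500,
                    f_yfp_membrane_raw = 500, is_wt_reference = TRUE)
  u <- compute_rho(normalize_to_plate(uni, plate_normalizer(uni)))
  expect_equal(u$rho, 1)
})

test_that("non-positive mCherry reference excludes the cell from rho", {
  cells <- make_measured_cells()
  cells$f_mcherry_cell_raw[4] <- 0
  out <- compute_rho(normalize_to_plate(cells, plate_normalizer(cells)))
  expect_true(out$excluded[4])
  expect_identical(out$exclusion_reason[4], "non-positive-reference")
  expect_true(is.na(out$rho[4]))
})

test_that("log transform and plate means follow the logarithm oracle", {
  cells <- data.frame(
    label = 1:3, excluded = FALSE, exclusion_reason = NA_character_,
    plate_id = "p1", genotype = "WT",
    f_mcherry_cell = 1, f_yfp_cell = 1, f_yfp_membrane = 1,
    rho = c(0.1, 1, 10), factor_membrane = 1, factor_stability = 1)
  out <- log_rho(cells)
  expect_equal(out$log10_rho, c(-1, 0, 1))
  expect_equal(log_rho(transform(cells, rho = 0.25))$log10_rho[1],
               log10(0.25), tolerance = 1e-12)
  s <- summarize_cells(out, by = c("plate_id", "genotype"))
  expect_equal(s$mean_log10_rho, 0)  # symmetric {0.1, 1, 10}
  expect_identical(s$n_cells, 3L)
  # rho <= 0 excluded from log statistics
  bad <- log_rho(transform(cells, rho = c(1, 0, 2)))
  expect_true(bad$excluded[2])
  expect_identical(bad$exclusion_reason[2], "non-positive-rho")
})
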