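#' Paired or independent comparisons with multiple-testing correction
#'
#' Compares a per-plate summary metric between genotype/condition groups.
#' Paired comparisons pair the two group values measured on the same plate;
#' the declared set of comparisons forms one multiple-testing family, adjusted
#' with Bonferroni or Benjamini-Hochberg. The significance level is
#' prespecified at alpha = 0.05.
#'
#' @param table `data.frame` with one row per plate x group (e.g. from
#'   [summarize_cells()]).
#' @param pairs List of length-2 character vectors, each a comparison
#'   `c(group_a, group_b)`.
#' @param metric Name of the numeric column to compare.
#' @param group_col Column holding the group labels.
#' @param id_col Column identifying the plate (pairing unit).
#' @param correction `"bonferroni"`, `"bh"` or `"none"`.
#' @param paired Paired t test (default) or independent.
#' @param var_equal For independent tests: Student's equal-variance t test
#'   (default) or Welch when `FALSE`.
#' @return `data.frame` with one row per comparison: `comparison`, `n_pairs`,
#'   `mean_difference`, `t`, `df`, `p_raw`, `p_adj`, `method`, `note`.
#' @export
paired_compare <- function(table, pairs, metric = "mean_log10_rho",
                           group_col = "genotype", id_col = "plate_id",
                           correction = c("bonferroni", "bh", "none"),
                           paired = TRUE, var_equal = TRUE) {
  correction <- match.arg(correction)
  if (!is.list(pairs)) pairs <- list(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- table[table[[group_col]] == pr[1], c(id_col, metric)]
    b <- table[table[[group_col]] == pr[2], c(id_col, metric)]
    note <- NA_character_
    if (paired) {
      m <- merge(a, b, by = id_col, suffixes = c("_a", "_b"))
      m <- m[complete.cases(m), , drop = FALSE]
      if (nrow(m) < 2L) {
        stop(sprintf("insufficient-pairs: comparison %s vs %s has %d complete pair(s)",
                     pr[1], pr[2], nrow(m)))
      }
      d <- m[[paste0(metric, "_a")]] - m[[paste0(metric, "_b")]]
      if (sd(d) <= 1e-12 * max(abs(mean(d)), 1)) {
        # degenerate: zero within-pair variance; t undefined
        note <- "zero-variance"
        tt <- list(statistic = NaN, parameter = length(d) - 1,
                   p.value = if (abs(mean(d)) <= 1e-12) 1 else 0,
                   estimate = mean(d))
      } else {
        tt <- t.test(d)
      }
      data.frame(comparison = paste(pr[1], "vs", pr[2]), n_pairs = nrow(m),
                 mean_difference = unname(tt$estimate),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, note = note, stringsAsFactors = FALSE)
    } else {
      x <- a[[metric]][!is.na(a[[metric]])]
      y <- b[[metric]][!is.na(b[[metric]])]
      if (length(x) < 2L || length(y) < 2L) {
        stop("insufficient-pairs: need >= 2 observations per group")
      }
      tt <- t.test(x, y, var.equal = var_equal)
      data.frame(comparison = paste(pr[1], "vs", pr[2]),
                 n_pairs = min(length(x), length(y)),
                 mean_difference = mean(x) - mean(y),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, note = note, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  method <- switch(correction, bonferroni = "bonferroni", bh = "BH",
                   none = "none")
  out$p_adj <- p.adjust(out$p_raw, method = method)
  out$method <- paste0(if (paired) "paired t" else
                         if (var_equal) "Student t" else "Welch t",
                       " + ", correction)
  out[, c("comparison", "n_pairs", "mean_difference", "t", "df",
          "p_raw", "p_adj", "method", "note")]
}

#' Within-plate genotype differences across temperatures
#'
#' For each plate carrying both genotypes, computes the difference
#' `metric(a) - metric(b)` (e.g. WT minus F508del mean log10 rho). When a
#' temperature column is present with two levels, the difference sets are
#' compared between temperatures with an independent t test (temperature can
#' only vary between plates, so within-plate pairing is impossible there).
#'
#' @param table Per-plate summary table.
#' @param genotype_a,genotype_b Group labels; differences are `a - b`.
#' @param metric Numeric column to difference.
#' @param group_col,id_col,temp_col Column names.
#' @param var_equal Student (default) vs Welch for the cross-temperature test.
#' @return List with `differences` (`id`, `temperature`, `difference`) and
#'   `test` (`data.frame` or `NULL` when fewer than two temperature groups).
#'   Plates missing either genotype are skipped and listed in `skipped`.
#' @export
within_plate_difference <- function(table, genotype_a, genotype_b,
                                    metric = "mean_log10_rho",
                                    group_col = "genotype",
                                    id_col = "plate_id",
                                    temp_col = "temperature",
                                    var_equal = TRUE) {
  ids <- unique(table[[id_col]])
  diffs <- list(); skipped <- character()
  for (id in ids) {
    sub <- table[table[[id_col]] == id, , drop = FALSE]
    va <- sub[[metric]][sub[[group_col]] == genotype_a]
    vb <- sub[[metric]][sub[[group_col]] == genotype_b]
    if (length(va) != 1L || length(vb) != 1L || is.na(va) || is.na(vb)) {
      skipped <- c(skipped, as.character(id))
      next
    }
    temp <- if (temp_col %in% names(sub)) sub[[temp_col]][1] else NA
    diffs[[length(diffs) + 1L]] <- data.frame(
      id = id, temperature = temp, difference = va - vb,
      stringsAsFactors = FALSE)
  }
  if (length(diffs) == 0L) stop("no plate carries both genotypes")
  d <- do.call(rbind, diffs)
  test <- NULL
  temps <- unique(d$temperature[!is.na(d$temperature)])
  if (length(temps) == 2L) {
    x <- d$difference[d$temperature == temps[1]]
    y <- d$difference[d$temperature == temps[2]]
    if (length(x) >= 2L && length(y) >= 2L) {
      tt <- tryCatch(t.test(x, y, var.equal = var_equal),
                     error = function(e) NULL)  # constant data: t undefined
      test <- data.frame(
        comparison = paste0(genotype_a, "-", genotype_b, ": ",
                            temps[1], " vs ", temps[2]),
        mean_1 = mean(x), mean_2 = mean(y), n_1 = length(x), n_2 = length(y),
        t = if (is.null(tt)) NaN else unname(tt$statistic),
        df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
        p = if (is.null(tt)) NA_real_ else tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(differences = d, test = test, skipped = skipped)
}

#' Hill dose-response fit with unit Hill coefficient
#'
#' Least-squares fit of
#' `response = floor + (ceiling - floor) * d / (d + EC50)` — the
#' four-parameter Hill equation with the Hill coefficient constrained to 1.
#' At `d = EC50` the response is exactly halfway between floor and ceiling.
#'
#' @param doses Dose levels (nM), >= 4 levels spanning the transition.
#' @param responses Measured responses (same length).
#' @return Object of class `dose_response_fit`: `ec50`, `ec50_se`, `floor`,
#'   `ceiling`, `hill_n` (1), `se` (named vector), `rss`, `fitted`.
#' @export
hill_fit <- function(doses, responses) {
  if (length(doses) != length(responses)) stop("length mismatch")
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 4L) stop("need >= 4 dose levels")
  if (diff(range(responses)) <= .Machine$double.eps^0.5 * max(1, abs(mean(responses)))) {
    stop("ec50-unidentifiable: responses are flat across doses")
  }
  fl0 <- min(responses); ce0 <- max(responses)
  half <- (fl0 + ce0) / 2
  ec0 <- doses[which.min(abs(responses - half))]
  ec0 <- max(ec0, min(doses[doses > 0], na.rm = TRUE))
  fit <- minpack.lm::nlsLM(
    responses ~ fl + (ce - fl) * doses / (doses + ec50),
    start = list(fl = fl0, ce = ce0, ec50 = ec0),
    lower = c(fl = -Inf, ce = -Inf, ec50 = .Machine$double.xmin),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(cf)))
  structure(list(
    ec50 = unname(cf["ec50"]), ec50_se = unname(se["ec50"]),
    floor = unname(cf["fl"]), ceiling = unname(cf["ce"]), hill_n = 1,
    se = se, rss = sum(residuals(fit)^2), fitted = fitted(fit),
    doses = doses, responses = responses
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> EC50 = %.4g +/- %.3g nM (floor %.3g, ceiling %.3g, n_H = 1)\n",
              x$ec50, x$ec50_se, x$floor, x$ceiling))
  invisible(x)
}

#' Linear fit / interpolation with x-axis intercept
#'
#' Fits `y = slope * x + constant` either by ordinary least squares
#' (`"regression"`) or as the exact line through two points (`"two-point"`,
#' e.g. anchoring a reference line through a known x-intercept and the
#' wild-type point). Reports the x-axis intercept `-constant / slope`, the
#' empirical relationship used to extrapolate conductance-vs-rho plots to the
#' membrane-proximity floor.
#'
#' @param x,y Numeric vectors; >= 3 points for regression, exactly/at least 2
#'   for two-point mode (the first and last point are used).
#' @param mode `"regression"` or `"two-point"`.
#' @return Object of class `linear_fit`: `slope`, `constant`, `x_intercept`
#'   (`NA` with `zero_slope = TRUE` when the slope vanishes), `r_squared`
#'   (regression only), `x`, `y`.
#' @export
#' @examples
#' linear_interpolation(c(0.3, 0.5), c(281.7 * 0.3 - 63.7, 281.7 * 0.5 - 63.7),
#'                      mode = "two-point")$x_intercept  # ~0.226
linear_interpolation <- function(x, y, mode = c("regression", "two-point")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("length mismatch")
  if (mode == "two-point") {
    if (length(x) < 2L) stop("two-point mode needs >= 2 points")
    x2 <- x[c(1L, length(x))]; y2 <- y[c(1L, length(y))]
    if (x2[1] == x2[2]) stop("two-point mode needs distinct x values")
    slope <- (y2[2] - y2[1]) / (x2[2] - x2[1])
    constant <- y2[1] - slope * x2[1]
    r2 <- NA_real_
  } else {
    if (length(x) < 3L) stop("regression needs >= 3 points")
    fit <- lm(y ~ x)
    slope <- unname(coef(fit)[2]); constant <- unname(coef(fit)[1])
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss == 0) NA_real_ else 1 - sum(residuals(fit)^2) / tss
  }
  zero <- !is.finite(slope) || slope == 0
  structure(list(slope = slope, constant = constant,
                 x_intercept = if (zero) NA_real_ else -constant / slope,
                 zero_slope = zero, r_squared = r2, x = x, y = y),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope = %.4g, constant = %.4g, x-intercept = %.4g\n",
              x$slope, x$constant, x$x_intercept))
  invisible(x)
}

#' Fold potentiation by acute VX-770
#'
#' Ratio of expression-normalized conductance measured with potentiator +
#' forskolin over forskolin alone, per genotype; genotypes exceeding the
#' threshold (default 20-fold) are flagged as strongly potentiated.
#'
#' @param table `data.frame` with columns `genotype`, `condition`,
#'   `G_CFTR_norm`.
#' @param condition_potentiated,condition_baseline Condition labels.
#' @param threshold Flagging threshold on the ratio.
#' @return `data.frame`: `genotype`, `g_baseline`, `g_potentiated`,
#'   `fold_potentiation` (`NA` + `undefined = TRUE` for non-positive
#'   baselines), `flagged`.
#' @export
fold_potentiation <- function(table,
                              condition_potentiated = "forskolin_vx770",
                              condition_baseline = "forskolin",
                              threshold = 20) {
  genotypes <- unique(table$genotype)
  rows <- lapply(genotypes, function(g) {
    gb <- table$G_CFTR_norm[table$genotype == g &
                              table$condition == condition_baseline]
    gp <- table$G_CFTR_norm[table$genotype == g &
                              table$condition == condition_potentiated]
    if (length(gb) == 0L || length(gp) == 0L) return(NULL)
    gb <- mean(gb); gp <- mean(gp)
    undef <- !is.finite(gb) || gb <= 0
    ratio <- if (undef) NA_real_ else gp / gb
    data.frame(genotype = g, g_baseline = gb, g_potentiated = gp,
               fold_potentiation = ratio, undefined = undef,
               flagged = !undef && ratio > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no genotype has both activation conditions")
  out
}

#' Correlate assay metrics against an external data set
#'
#' Ordinary least-squares regression of an external measurement (e.g.
#' published complex-glycosylation fractions or short-circuit currents) on
#' this assay's metric, matched by genotype, with r^2 and the 95% confidence
#' band of the regression line.
#'
#' @param x `data.frame` with `genotype` and `value` (this assay).
#' @param y `data.frame` with `genotype` and `value` (external metric).
#' @return List: `r_squared`, `slope`, `intercept`, `n`, `fit` (the `lm`),
#'   `band` (`data.frame` of `x`, `fit`, `lwr`, `upr` on a grid).
#' @export
external_correlation <- function(x, y) {
  m <- merge(x, y, by = "genotype", suffixes = c("_assay", "_external"))
  m <- m[complete.cases(m[, c("value_assay", "value_external")]), ,
         drop = FALSE]
  if (nrow(m) < 3L) stop("need >= 3 matched genotypes")
  fit <- lm(value_external ~ value_assay, data = m)
  grid <- data.frame(value_assay = seq(min(m$value_assay),
                                       max(m$value_assay), length.out = 50))
  pr <- suppressWarnings(
    predict(fit, newdata = grid, interval = "confidence", level = 0.95))
  tss <- sum((m$value_external - mean(m$value_external))^2)
  list(r_squared = if (tss == 0) NA_real_ else
         1 - sum(residuals(fit)^2) / tss,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = nrow(m), fit = fit,
       band = data.frame(x = grid$value_assay, fit = pr[, "fit"],
                         lwr = pr[, "lwr"], upr = pr[, "upr"]))
}
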