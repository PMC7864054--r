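make_summary <- function(a, b, metric = "mean_log10_rho") {
  data.frame(plate_id = rep(seq_along(a), 2),
             genotype = rep(c("WT", "F508del"), each = length(a)),
             stats::setNames(data.frame(c(a, b)), metric),
             stringsAsFactors = FALSE)
}

test_that("paired t matches the closed-form oracle and corrections are exact", {
  # fixture pairs {(1,2),(1.1,2.2),(0.9,1.9)}
  a <- c(1, 1.1, 0.9); b <- c(2, 2.2, 1.9)
  tab <- make_summary(b, a)  # WT = b, F508del = a; compare WT vs F508del
  res <- paired_compare(tab, list(c("WT", "F508del")), correction = "none")
  d <- b - a
  t_oracle <- mean(d) / (sd(d) / sqrt(3))
  p_oracle <- 2 * pt(abs(t_oracle), df = 2, lower.tail = FALSE)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_raw, p_oracle, tolerance = 1e-12)
  expect_equal(res$mean_difference, mean(d))

  # Bonferroni on 3 simultaneous comparisons: p_adj = min(1, 3 p)
  tab3 <- rbind(make_summary(c(1, 2, 3, 4), c(1.5, 2.1, 3.4, 4.2)))
  res3 <- paired_compare(tab3, list(c("WT", "F508del"), c("WT", "F508del"),
                                    c("WT", "F508del")),
                         correction = "bonferroni")
  expect_equal(res3$p_adj, pmin(1, 3 * res3$p_raw))
})

test_that("identical paired values give zero difference and p = 1", {
  tab <- make_summary(c(1, 2, 3), c(1, 2, 3))
  res <- paired_compare(tab, list(c("WT", "F508del")), correction = "none")
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p_raw, 1)
  expect_identical(res$note, "zero-variance")
})

test_that("too few complete pairs raises insufficient-pairs", {
  tab <- make_summary(1, 2)
  expect_error(paired_compare(tab, list(c("WT", "F508del"))),
               "insufficient-pairs")
})

test_that("multiple-testing corrections are ordered Bonferroni >= BH >= raw", {
  set.seed(9)
  tabs <- make_summary(rnorm(6, 1), rnorm(6, 1.2))
  prs <- list(c("WT", "F508del"))
  fam <- do.call(rbind, lapply(1:6, function(i) {
    tab <- make_summary(rnorm(5, 1, 0.3), rnorm(5, 1 + 0.1 * i, 0.3))
    tab
  }))
  # build a 6-comparison family from shifted fixtures
  tabs <- lapply(1:6, function(i) make_summary(rnorm(5, 1, 0.3),
                                               rnorm(5, 1 + 0.15 * i, 0.3)))
  raw <- vapply(tabs, function(tb) {
    paired_compare(tb, prs, correction = "none")$p_raw
  }, numeric(1))
  bonf <- p.adjust(raw, "bonferroni"); bh <- p.adjust(raw, "BH")
  expect_true(all(bonf >= bh - 1e-15))
  expect_true(all(bh >= raw - 1e-15))
  # BH adjusted p-values are monotone along sorted raw p-values
  ord <- order(raw)
  expect_true(all(diff(bh[ord]) >= -1e-15))
})

test_that("within-plate differences recover a constructed shift and detect temperature effects", {
  tab <- data.frame(plate_id = rep(1:6, each = 2),
                    genotype = rep(c("WT", "F508del"), 6),
                    temperature = rep(c(37, 28), each = 6),
                    mean_log10_rho = rep(c(1, 0.4), 6))
  wd <- within_plate_difference(tab, "WT", "F508del")
  expect_equal(wd$differences$difference, rep(0.6, 6))

  # identical genotypes: all differences zero
  tab0 <- transform(tab, mean_log10_rho = rep(1, 12))
  expect_equal(within_plate_difference(tab0, "WT", "F508del")$differences$difference,
               rep(0, 6))

  # power check: shifted difference sets separate at alpha = 0.05
  set.seed(21)
  n <- 8
  mk <- function(temp, delta) {
    data.frame(plate_id = paste0(temp, "_", 1:n),
               genotype = rep(c("WT", "F508del"), each = n),
               temperature = temp,
               mean_log10_rho = c(rnorm(n, 1, 0.05),
                                  rnorm(n, 1 - delta, 0.05)))
  }
  tab2 <- rbind(mk(37, 0.8), mk(28, 0.4))
  wd2 <- within_plate_difference(tab2, "WT", "F508del")
  expect_lt(wd2$test$p, 0.05)

  # plates missing a genotype are skipped and logged
  tab3 <- tab[-1, ]
  wd3 <- within_plate_difference(tab3, "WT", "F508del")
  expect_identical(wd3$skipped, "1")
  expect_equal(nrow(wd3$differences), 5)
})

test_that("Hill fits with unit coefficient recover noise-free parameters", {
  d <- c(1, 3, 10, 30, 100, 300, 1000, 3000)
  truth <- list(fl = 0.2, ce = 5, ec50 = 114)
  y <- truth$fl + (truth$ce - truth$fl) * d / (d + truth$ec50)
  fit <- hill_fit(d, y)
  expect_equal(fit$ec50, 114, tolerance = 114 * 0.001)
  expect_equal(fit$floor, 0.2, tolerance = 0.001)
  expect_equal(fit$ceiling, 5, tolerance = 0.005)
  expect_identical(fit$hill_n, 1)
  # response at d = EC50 is the midpoint
  mid <- fit$floor + (fit$ceiling - fit$floor) * fit$ec50 / (fit$ec50 + fit$ec50)
  expect_equal(mid, (fit$floor + fit$ceiling) / 2)
  expect_error(hill_fit(d, rep(1, 8)), "ec50-unidentifiable")
  expect_error(hill_fit(c(1, 10, 100), c(0, 1, 2)), "4 dose")
})

test_that("linear fits expose slope, constant and x-intercept consistently", {
  lf <- linear_interpolation(c(0, 1), c(0, 1), mode = "two-point")
  expect_equal(lf$slope, 1); expect_equal(lf$constant, 0)
  expect_equal(lf$x_intercept, 0)
  # x_intercept * slope + constant == 0 whenever defined
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(1) * x + rnorm(1) + rnorm(5, 0, 0.1)
    f <- linear_interpolation(x, y)
    if (!f$zero_slope) {
      expect_equal(f$x_intercept * f$slope + f$constant, 0, tolerance = 1e-9)
    }
  }
  zf <- linear_interpolation(c(0, 1), c(2, 2), mode = "two-point")
  expect_true(zf$zero_slope)
  expect_true(is.na(zf$x_intercept))
  # regression r_squared = 1 on exact data
  rf <- linear_interpolation(1:5, 2 * (1:5) - 1)
  expect_equal(rf$r_squared, 1)
})

test_that("fold potentiation is elementwise division with flagging", {
  tab <- data.frame(
    genotype = rep(c("A", "B", "C"), each = 2),
    condition = rep(c("forskolin", "forskolin_vx770"), 3),
    G_CFTR_norm = c(1, 1, 2, 42, 0, 5))
  fp <- fold_potentiation(tab)
  expect_equal(fp$fold_potentiation[fp$genotype == "A"], 1)
  expect_equal(fp$fold_potentiation[fp$genotype == "B"], 21)
  expect_true(fp$flagged[fp$genotype == "B"])
  expect_false(fp$flagged[fp$genotype == "A"])
  expect_true(fp$undefined[fp$genotype == "C"])
  expect_true(is.na(fp$fold_potentiation[fp$genotype == "C"]))
})

test_that("external correlation reproduces closed-form r^2", {
  x <- data.frame(genotype = letters[1:6], value = c(1, 2, 3, 4, 5, 6))
  y <- data.frame(genotype = letters[1:6], value = 2 * c(1, 2, 3, 4, 5, 6))
  expect_equal(external_correlation(x, y)$r_squared, 1)
  set.seed(8)
  y2 <- data.frame(genotype = letters[1:6],
                   value = 3 * x$value + rnorm(6, 0, 0.5))
  res <- external_correlation(x, y2)
  r2_oracle <- cor(x$value, y2$value)^2
  expect_equal(res$r_squared, r2_oracle, tolerance = 1e-12)
  expect_true(all(res$band$lwr <= res$band$fit & res$band$fit <= res$band$upr))
  expect_error(external_correlation(x[1:2, ], y[1:2, ]), "3 matched")
})
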