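test_that("trace normalization uses the last pre-iodide frame", {
  tr <- normalize_trace(c(0, 2, 4), c(100, 100, 50), t_iodide = 3)
  expect_equal(tr$f_norm, c(1, 1, 0.5))
  # constant series stays at 1
  trc <- normalize_trace(seq(0, 20, 2), rep(250, 11), t_iodide = 9)
  expect_true(all(trc$f_norm == 1))
  # element-wise division oracle on an arbitrary series
  set.seed(5)
  raw <- 900 * exp(-seq(0, 2, length.out = 21)) + rnorm(21, 0, 5)
  tr2 <- normalize_trace(seq(0, 40, 2), raw, t_iodide = 5)
  expect_equal(tr2$f_norm, raw / raw[3])
  expect_error(normalize_trace(c(0, 2), c(1, 2), t_iodide = 0),
               "bad-reference-frame")
  expect_error(normalize_trace(c(0, 2, 4), c(0, 1, 1), t_iodide = 1),
               "bad-reference-frame")
})

test_that("entry rate recovers hand-computed finite differences", {
  # constant f -> all rates 0
  tr <- structure(list(times = seq(0, 10, 2), f_norm = rep(1, 6),
                       t_iodide = 0, t_activation = NA_real_,
                       iodide_out = 100, f_mcherry_well = 1),
                  class = "quench_trace")
  er <- entry_rate(tr)
  expect_equal(er$max_rate, 0)
  # [I-] rising 0 -> 1 mM over one 2-s step: 0.5 mM/s
  f1 <- fluorescence_from_iodide(c(0, 1, 1, 1, 1, 1))
  tr2 <- tr; tr2$f_norm <- f1
  expect_equal(entry_rate(tr2)$max_rate, 0.5, tolerance = 1e-12)
  expect_error(entry_rate(structure(list(times = 0, f_norm = 1, t_iodide = 0,
                                         t_activation = NA_real_),
                                    class = "quench_trace")),
               "trace-too-short")
})

test_that("maximum entry rate agrees with the dense-grid model derivative", {
  p <- quench_params(0.3, -60, 0, 5)
  coarse <- simulate_quench(p, duration = 40, dt_sample = 2)
  er <- entry_rate(coarse)
  dense <- simulate_quench(p, duration = 40, dt_sample = 0.01)
  true_max <- max(diff(dense$iodide_in) / 0.01)
  expect_lt(abs(er$max_rate - true_max) / true_max, 0.05)
})

test_that("activation window restricts the rate search", {
  # decreasing conductance profile: early fast, late slow; window after 20 s
  p <- quench_params(0.1, -60, 2, 4)
  tr <- simulate_quench(p, duration = 60)
  tr$t_activation <- 20
  er_win <- entry_rate(tr)
  tr$t_activation <- NA_real_
  er_all <- entry_rate(tr)
  expect_lt(er_win$max_rate, er_all$max_rate)
})

test_that("expression normalization is plain division with guards", {
  expect_equal(normalize_rate(0.4, 1), 0.4)
  expect_equal(normalize_rate(0.4, 2), 0.2)
  rates <- c(0.1, 0.5, 1.2); norms <- c(0.5, 1, 2)
  expect_equal(normalize_rate(rates, norms), rates / norms)
  expect_error(normalize_rate(0.4, 0), "positive")
  expect_equal(normalize_conductance(2, 0.5), 4)
})

test_that("noise-free simulated traces are recovered to < 1% in all 4 parameters", {
  st <- make_traces(trace_spec(canonical_quench(), noise_sd = 0, seed = 7))
  fit <- fit_quench(st$traces$w1)
  expect_false(fit$constrained)
  truth <- canonical_quench()
  expect_equal(fit$params$G_CFTR, truth$G_CFTR, tolerance = 0.01)
  expect_equal(fit$params$V_M, truth$V_M, tolerance = 0.01 * abs(truth$V_M))
  expect_equal(fit$params$G_trans, truth$G_trans, tolerance = 0.01)
  expect_equal(fit$params$tau_trans, truth$tau_trans, tolerance = 0.05)
  expect_lt(fit$rss, 1e-10)
})

test_that("noisy recovery with negative-control averages is accurate (small n)", {
  ests <- vapply(1:12, function(i) {
    st <- make_traces(trace_spec(canonical_quench(), noise_sd = 0.01,
                                 seed = 2000 + i))
    fit_quench(st$traces$w1,
               control_averages = c(G_trans = 0.5, tau_trans = 5))$params$G_CFTR
  }, numeric(1))
  expect_lt(abs(median(ests) - 1), 0.1)
})

test_that("fast quench triggers the constrained fallback and errors without controls", {
  st <- make_traces(trace_spec(
    data.frame(well = "w1", G_CFTR = 20, V_M = -60, G_trans = 5,
               tau_trans = 2, f_mcherry_well = 1),
    noise_sd = 0.005, seed = 3))
  tr <- st$traces$w1
  # the fixture quenches below 0.2 within 3 post-iodide samples
  expect_lt(min(tr$f_norm[tr$times > 0][1:3]), 0.2)
  fit <- fit_quench(tr, control_averages = c(G_trans = 5, tau_trans = 2))
  expect_true(fit$constrained)
  expect_equal(fit$params$G_trans, 5)
  expect_equal(fit$params$tau_trans, 2)
  expect_error(fit_quench(tr), "control_averages")
})

test_that("constrained mode does not degrade recovery on fast-quench fixtures", {
  errs <- vapply(1:4, function(i) {
    st <- make_traces(trace_spec(
      data.frame(well = "w1", G_CFTR = 15, V_M = -60, G_trans = 4,
                 tau_trans = 2, f_mcherry_well = 1),
      noise_sd = 0.005, seed = 4000 + i))
    tr <- st$traces$w1
    con <- fit_quench(tr, control_averages = c(G_trans = 4, tau_trans = 2))
    # force the 4-parameter path by disabling the fast trigger
    free <- suppressWarnings(fit_quench(tr, fast_f = 0))
    c(abs(con$params$G_CFTR - 15), abs(free$params$G_CFTR - 15))
  }, numeric(2))
  expect_lte(median(errs[1, ]), median(errs[2, ]) + 0.15 * 15)
})

test_that("short traces are rejected", {
  st <- make_traces(trace_spec(canonical_quench(), noise_sd = 0,
                               duration = 20, seed = 1))
  expect_error(fit_quench(st$traces$w1), "40 s")
})
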