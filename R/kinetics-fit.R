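#' Normalize a raw YFP time series to the pre-iodide frame
#'
#' Divides the raw fluorescence by the value at the last sample strictly
#' before the iodide addition (`F_YFPmax`), so the normalized trace equals 1
#' at that sample.
#'
#' @param times Sample times (s), strictly increasing.
#' @param raw Raw YFP intensities (same length as `times`).
#' @param t_iodide Time of extracellular iodide addition (s).
#' @param t_activation Time of activator addition (s); `NA` when the trace was
#'   pre-activated (steady-state protocol).
#' @param iodide_out Extracellular iodide after addition (mM).
#' @param f_mcherry_well Mean within-cell mCherry of the well, normalized to
#'   same-plate wild type (used later for expression normalization).
#' @return Object of class `quench_trace`: list with `times`, `f_norm`,
#'   `t_iodide`, `t_activation`, `iodide_out`, `f_mcherry_well`.
#' @export
#' @examples
#' tr <- normalize_trace(c(0, 2, 4), c(100, 100, 50), t_iodide = 3)
#' tr$f_norm  # 1, 1, 0.5
normalize_trace <- function(times, raw, t_iodide, t_activation = NA_real_,
                            iodide_out = 100, f_mcherry_well = NA_real_) {
  if (length(times) != length(raw)) stop("`times` and `raw` lengths differ")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing")
  }
  ref_idx <- which(times < t_iodide)
  if (length(ref_idx) == 0L) {
    stop("bad-reference-frame: no sample strictly before `t_iodide`")
  }
  ref <- raw[max(ref_idx)]
  if (!is.finite(ref) || ref <= 0) {
    stop("bad-reference-frame: reference sample must be positive")
  }
  structure(list(times = times, f_norm = raw / ref, t_iodide = t_iodide,
                 t_activation = t_activation, iodide_out = iodide_out,
                 f_mcherry_well = f_mcherry_well),
            class = "quench_trace")
}

#' @export
print.quench_trace <- function(x, ...) {
  cat(sprintf("<quench_trace> %d samples, t_iodide = %g s, F range [%.3f, %.3f]\n",
              length(x$times), x$t_iodide, min(x$f_norm), max(x$f_norm)))
  invisible(x)
}

#' Iodide-entry rate series and its maximum
#'
#' Converts the post-iodide samples to intracellular iodide (clipping F > 1 to
#' 1 and dropping fully quenched samples with F <= 0), takes consecutive
#' finite differences divided by the sampling interval, and reports the
#' maximum over the activation window (samples at/after `t_activation`; the
#' whole post-iodide trace when `t_activation` is `NA`, e.g. DMSO controls use
#' the same window as activated wells).
#'
#' @param trace A `quench_trace`.
#' @param constants A [kinetics_constants()] object.
#' @param smooth If `TRUE`, apply a 3-point moving average to the rate series
#'   before taking the maximum (off by default; the raw consecutive
#'   differences define the estimator).
#' @return List with `times` (interval end times), `rate` (mM/s) and
#'   `max_rate` (mM/s).
#' @export
entry_rate <- function(trace, constants = kinetics_constants(),
                       smooth = FALSE) {
  post <- trace$times >= trace$t_iodide
  times <- trace$times[post]
  f <- trace$f_norm[post]
  keep <- f > 0
  if (any(!keep)) warning("dropping fully quenched samples (F <= 0)")
  times <- times[keep]
  f <- pmin(f, 1)
  if (length(f) < 2L) stop("trace-too-short: need >= 2 post-iodide samples")
  cin <- constants$K_I * (1 - f) / f
  dt <- diff(times)
  rate <- diff(cin) / dt
  rate_times <- times[-1]
  use <- rate
  if (smooth && length(rate) >= 3L) {
    use <- stats::filter(rate, rep(1 / 3, 3), sides = 2)
    use[is.na(use)] <- rate[is.na(use)]
    use <- as.numeric(use)
  }
  window <- if (is.na(trace$t_activation)) rep(TRUE, length(rate_times))
            else rate_times >= trace$t_activation
  if (!any(window)) stop("no samples in the activation window")
  list(times = rate_times, rate = rate, max_rate = max(use[window]))
}

#' Normalize a maximal entry rate by well mCherry expression
#'
#' @param max_rate Maximal iodide-entry rate (mM/s).
#' @param f_mcherry_well Mean within-cell mCherry of the well, already
#'   normalized to same-plate wild type; must be > 0.
#' @return Expression-normalized rate, `max_rate / f_mcherry_well`.
#' @export
normalize_rate <- function(max_rate, f_mcherry_well) {
  if (any(!is.finite(f_mcherry_well)) || any(f_mcherry_well <= 0)) {
    stop("`f_mcherry_well` must be positive")
  }
  max_rate / f_mcherry_well
}

# Condition number of the correlation-scaled J'J matrix from an nls.lm fit;
# Inf when any diagonal entry vanishes (parameter with no leverage).
scaled_condition <- function(hessian) {
  d <- sqrt(diag(hessian))
  if (any(!is.finite(d)) || any(d == 0)) return(Inf)
  s <- hessian / outer(d, d)
  kappa(s, exact = TRUE)
}

#' Fit the quench forward model to an observed trace
#'
#' Estimates the four model parameters (`G_CFTR`, `V_M`, `G_trans`,
#' `tau_trans`) by bounded nonlinear least squares on the post-iodide
#' normalized fluorescence, minimizing the sum of squared residuals between
#' the observed trace and the model-predicted fraction of anion-free
#' chromophore. Multiple jittered restarts guard against local minima.
#'
#' The four parameters are weakly identifiable from a single 40-s trace: a
#' low `G_CFTR` with depolarized `V_M` and a large slow transient can mimic
#' the true curve at comparable residual error. When the trace does not carry
#' enough information to identify all four parameters, the fit falls back to
#' fixing `G_trans` and `tau_trans` at the supplied negative-control averages
#' with only `G_CFTR` and `V_M` free. The fallback is used when any of these
#' hold: (i) the quench is too fast (F drops below `fast_f`, default 0.3,
#' within the first three post-iodide samples); (ii) the correlation-scaled
#' curvature matrix of the 4-parameter fit is ill-conditioned (condition
#' number above `cond_max`); or (iii) negative-control averages are available
#' and the 4-parameter fit does not improve significantly on the constrained
#' fit by the extra-sum-of-squares F test at the prespecified alpha = 0.05 —
#' i.e. the data do not support freeing the transient parameters.
#'
#' @param trace A `quench_trace` covering at least 40 s after iodide addition.
#' @param constants A [kinetics_constants()] object.
#' @param control_averages Optional `c(G_trans = , tau_trans = )` averages
#'   from negative-control wells, used by the constrained fallback.
#' @param lower,upper Parameter bounds, in the order
#'   (G_CFTR nS, V_M mV, G_trans nS, tau_trans s).
#' @param n_starts Number of starts (1 default + jittered restarts).
#' @param seed Seed for the restart jitter (fixed for reproducibility).
#' @param fast_f Fast-quench threshold on F within the first 3 post-iodide
#'   samples.
#' @param cond_max Condition-number threshold for the identifiability check.
#' @param f_alpha Significance level of the extra-sum-of-squares F test
#'   comparing the 4-parameter fit against the constrained fit.
#' @return Object of class `quench_fit`: `params` ([quench_params()]),
#'   `constrained` flag, `rss`, `condition` (scaled condition number of the
#'   free-parameter curvature), `fitted` (model trace on the data grid),
#'   `n_obs`, `convergence` info.
#' @export
fit_quench <- function(trace, constants = kinetics_constants(),
                       control_averages = NULL,
                       lower = c(G_CFTR = 0, V_M = -100, G_trans = 0,
                                 tau_trans = 0.5),
                       upper = c(G_CFTR = 100, V_M = 20, G_trans = 100,
                                 tau_trans = 60),
                       n_starts = 5, seed = 1,
                       fast_f = 0.3, cond_max = 1e6, f_alpha = 0.05) {
  post <- trace$times >= trace$t_iodide & trace$f_norm > 0
  tpost <- trace$times[post] - trace$t_iodide
  fobs <- trace$f_norm[post]
  if (max(tpost) < 40) {
    stop("trace must cover >= 40 s after iodide addition")
  }

  sim_grid <- function(p) {
    rhs <- function(t, y, parms) list(model_rate(t, y[1], p, constants))
    sol <- deSolve::ode(c(cin = 0), times = tpost, func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-10)
    fluorescence_from_iodide(pmax(sol[, "cin"], 0), constants)
  }
  resid4 <- function(par) {
    fobs - sim_grid(quench_params(par[1], par[2], par[3], par[4]))
  }
  resid2 <- function(par) {
    fobs - sim_grid(quench_params(par[1], par[2],
                                  control_averages[["G_trans"]],
                                  control_averages[["tau_trans"]]))
  }

  # crude initial-slope heuristic for G_CFTR (rate ~ 0.4 mM/s per nS at -60 mV)
  f2 <- max(min(fobs[min(2L, length(fobs))], 1), 0.05)
  slope0 <- constants$K_I * (1 - f2) / f2 / max(tpost[2], constants$dt)
  g0 <- min(max(slope0 / 0.4, 0.05), 50)
  start4 <- c(G_CFTR = g0, V_M = -60, G_trans = g0 / 4, tau_trans = 5)

  run_starts <- function(resid_fn, start, lo, up, n) {
    starts <- list(start)
    if (n > 1) {
      jit <- with_seed_if(seed, lapply(seq_len(n - 1), function(i) {
        s <- start * exp(rnorm(length(start), 0, 0.5))
        s["V_M"] <- start["V_M"] + rnorm(1, 0, 15)
        pmin(pmax(s, lo + 1e-6), up - 1e-6)
      }))
      starts <- c(starts, jit)
    }
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = pmin(pmax(s, lo), up), lower = lo, upper = up,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      confirmed <- !is.null(best) &&
        abs(fit$deviance - best$deviance) <= 1e-4 * max(best$deviance, 1e-12)
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
      if (best$deviance <= 1e-12 * length(fobs)) break
      if (confirmed) break  # an independent restart reproduced the optimum
    }
    if (is.null(best)) {
      stop("non-convergence: all restarts failed; check the trace and bounds")
    }
    best
  }

  fast <- any(fobs[seq_len(min(4L, length(fobs)))][-1] < fast_f)
  constrained <- FALSE
  fit <- NULL
  cond <- NA_real_

  if (fast && is.null(control_averages)) {
    stop(paste("quench too fast for a 4-parameter fit and no",
               "`control_averages` supplied for the constrained fallback"))
  }
  if (!fast) {
    fit <- run_starts(resid4, start4, lower, upper, n_starts)
    cond <- scaled_condition(fit$hessian)
  }
  if (!is.null(control_averages)) {
    use_constrained <- fast || cond > cond_max
    fit2 <- NULL
    if (!use_constrained) {
      # nested-model check: free G_trans/tau_trans only if they earn their keep
      fit2 <- run_starts(resid2, start4[1:2], lower[1:2], upper[1:2], n_starts)
      df2 <- length(fobs) - 4L
      fstat <- ((fit2$deviance - fit$deviance) / 2) /
        max(fit$deviance / df2, .Machine$double.eps)
      p_extra <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
      use_constrained <- p_extra >= f_alpha
    }
    if (use_constrained) {
      constrained <- TRUE
      fit <- if (is.null(fit2)) {
        run_starts(resid2, start4[1:2], lower[1:2], upper[1:2], n_starts)
      } else fit2
      cond <- scaled_condition(fit$hessian)
    }
  } else if (cond > cond_max) {
    warning("ill-conditioned 4-parameter fit and no control averages; ",
            "keeping the unconstrained estimates")
  }

  par <- fit$par
  params <- if (constrained) {
    quench_params(par[["G_CFTR"]], par[["V_M"]],
                  control_averages[["G_trans"]],
                  control_averages[["tau_trans"]])
  } else {
    quench_params(par[["G_CFTR"]], par[["V_M"]], par[["G_trans"]],
                  par[["tau_trans"]])
  }
  structure(list(
    params = params, constrained = constrained, rss = fit$deviance,
    condition = cond, fitted = sim_grid(params), times = tpost + trace$t_iodide,
    n_obs = length(fobs), convergence = fit$info
  ), class = "quench_fit")
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf(
    "<quench_fit>%s G_CFTR = %.3g nS, V_M = %.3g mV, G_trans = %.3g nS, tau = %.3g s (rss %.3g, n %d)\n",
    if (x$constrained) " [constrained]" else "", x$params$G_CFTR,
    x$params$V_M, x$params$G_trans, x$params$tau_trans, x$rss, x$n_obs))
  invisible(x)
}

#' Normalize a fitted conductance by well mCherry expression
#'
#' @param fit A [fit_quench()] result (or a bare G_CFTR value in nS).
#' @param f_mcherry_well Mean within-cell mCherry of the well, normalized to
#'   same-plate wild type; must be > 0.
#' @return `G_CFTR / f_mcherry_well` (nS per unit normalized mCherry).
#' @export
normalize_conductance <- function(fit, f_mcherry_well) {
  g <- if (inherits(fit, "quench_fit")) fit$params$G_CFTR else fit
  normalize_rate(g, f_mcherry_well)
}
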