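#' Filter-chain configuration
#'
#' Thresholds of the clinical candidate-curve filter chain.
#'
#' @param p_auc fraction of curves removed by the area filter (smallest
#'   areas removed first).
#' @param p_rough fraction removed by the roughness filter (roughest first).
#' @param pve_tol relative half-width of the steady-state/first-passage
#'   ratio acceptance band (0.20 = mean +/- 20 %).
#' @param steady_frac post-peak fraction of the maximum defining the steady
#'   state start (strictly below).
#' @param steady_len number of steady-state samples integrated.
#' @param baseline_end end of the pre-contrast window, seconds.
#' @return A `filter_config` object.
#' @export
filter_config <- function(p_auc = 0.90, p_rough = 0.25, pve_tol = 0.20,
                          steady_frac = 0.30, steady_len = 10,
                          baseline_end = 26) {
  stopifnot(p_auc >= 0, p_auc < 1, p_rough >= 0, p_rough < 1,
            pve_tol > 0, pve_tol < 1, steady_frac > 0, steady_frac < 1,
            steady_len >= 1)
  structure(list(p_auc = p_auc, p_rough = p_rough, pve_tol = pve_tol,
                 steady_frac = steady_frac, steady_len = as.integer(steady_len),
                 baseline_end = baseline_end),
            class = "filter_config")
}

filter_trace <- function(stage, n_in, n_out, removed) {
  stopifnot(n_out == n_in - length(removed))
  list(stage = stage, n_in = n_in, n_out = n_out, removed = removed)
}

#' Convert signal curves to tracer concentration
#'
#' Per curve, the baseline `S0` is the mean of the pre-contrast samples
#' (`t < baseline_end`) and `C(t) = -log(S(t)/S0) / (k * TE)`.  `k` defaults
#' to 1 (concentration in relaxation-rate units, the clinical convention);
#' passing the simulator's calibrated `k_const` expresses concentrations in
#' the arterial model units.  Signals at or below `eps * S0` are clipped to
#' `eps * S0` before the log; the default guard is small enough that no
#' positive noise-free signal is ever clipped.
#'
#' @param curves a signal [curve_set()].
#' @param te echo time, seconds.
#' @param baseline_end end of the pre-contrast window, seconds.
#' @param k_const proportionality constant dividing the relaxation change.
#' @param eps relative clipping floor for non-positive signals.
#' @return A concentration [curve_set()]; curves whose baseline mean is not
#'   positive are dropped and recorded in the `"trace"` attribute.
#' @export
signal_to_concentration <- function(curves, te, baseline_end = 26,
                                    k_const = 1, eps = 1e-12) {
  stopifnot(inherits(curves, "curve_set"), curves$kind == "signal",
            te > 0, k_const > 0)
  pre <- curves$grid$time < baseline_end
  if (sum(pre) < 2) stop("baseline window must contain at least 2 samples")
  s0 <- rowMeans(curves$values[, pre, drop = FALSE])
  ok <- s0 > 0
  vals <- curves$values[ok, , drop = FALSE]
  floorv <- eps * s0[ok]
  vals <- pmax(vals, floorv)           # column-recycled row floors
  conc <- -log(vals / s0[ok]) / (k_const * te)
  out <- curve_set(conc, curves$grid, ids = curves$ids[ok],
                   kind = "concentration")
  attr(out, "trace") <- filter_trace("signal_to_concentration",
                                     length(s0), sum(ok),
                                     curves$ids[!ok])
  out
}

#' Area-under-curve filter
#'
#' Removes the `floor(p_auc * N)` curves with the smallest trapezoidal area
#' under the whole curve; most voxels in a perfusion slice barely enhance
#' and this discards them wholesale.  Ties break by id order; surviving
#' curves keep their original order.
#'
#' @param curves a [curve_set()].
#' @param p_auc fraction removed.
#' @return The filtered [curve_set()] with a `"trace"` attribute.
#' @export
auc_filter <- function(curves, p_auc = 0.90) {
  n <- nrow(curves$values)
  if (n < 2) stop("need at least 2 curves")
  n_drop <- floor(p_auc * n)
  if (n_drop >= n) stop("p_auc removes every curve")
  if (n_drop == 0) {
    out <- curves
  } else {
    auc <- apply(curves$values, 1, trapz_auc, dt = curves$grid$dt)
    drop_ids <- curves$ids[order(auc, curves$ids)[seq_len(n_drop)]]
    out <- subset_curves(curves, setdiff(curves$ids, drop_ids))
  }
  attr(out, "trace") <- filter_trace("auc_filter", n, nrow(out$values),
                                     setdiff(curves$ids, out$ids))
  out
}

#' Curve roughness
#'
#' The integrated squared second derivative, discretised as
#' `sum(((C[i+1] - 2 C[i] + C[i-1]) / dt^2)^2) * dt`.  Zero for any affine
#' curve; noise inflates it sharply because second differences amplify
#' high-frequency content.
#'
#' @param curve curve values on a uniform grid.
#' @param dt sampling interval, seconds.
#' @return The roughness value (>= 0).
#' @export
roughness <- function(curve, dt = 1) {
  if (length(curve) < 3) stop("need at least 3 samples")
  d2 <- diff(curve, differences = 2) / dt^2
  sum(d2^2) * dt
}

#' Roughness filter
#'
#' Removes the `floor(p_rough * N)` roughest curves.  By default each curve
#' is first normalised to unit area, making the criterion a pure shape
#' measure: an irregular noisy curve is rough at any amplitude, while a
#' large smooth arterial curve is not penalised for its size.  Curves with
#' non-positive area count as infinitely rough.
#'
#' @param curves a [curve_set()].
#' @param p_rough fraction removed.
#' @param normalize normalise curves to unit area before measuring?
#' @return The filtered [curve_set()] with a `"trace"` attribute.
#' @export
roughness_filter <- function(curves, p_rough = 0.25, normalize = TRUE) {
  n <- nrow(curves$values)
  if (n < 2) stop("need at least 2 curves")
  n_drop <- floor(p_rough * n)
  if (n_drop == 0) {
    out <- curves
  } else {
    dt <- curves$grid$dt
    r <- vapply(seq_len(n), function(i) {
      y <- curves$values[i, ]
      if (normalize) {
        a <- trapz_auc(y, dt)
        if (a <= 0) return(Inf)
        y <- y / a
      }
      roughness(y, dt)
    }, numeric(1))
    drop_ids <- curves$ids[order(-r, curves$ids)[seq_len(n_drop)]]
    out <- subset_curves(curves, setdiff(curves$ids, drop_ids))
  }
  attr(out, "trace") <- filter_trace("roughness_filter", n, nrow(out$values),
                                     setdiff(curves$ids, out$ids))
  out
}

#' Start of the post-bolus steady state
#'
#' The first sample strictly after the peak whose value is strictly below
#' `frac` times the maximum.
#'
#' @param curve concentration curve.
#' @param grid the matching [time_grid()].
#' @param frac threshold fraction of the maximum.
#' @return The 1-based sample index, or `NA_integer_` if the curve never
#'   decays below the threshold before the end of the scan.
#' @export
steady_state_start <- function(curve, grid, frac = 0.30) {
  ip <- which.max(curve)
  hp <- curve[ip]
  idx <- which(grid$time > grid$time[ip] & curve < frac * hp)
  if (length(idx) == 0) return(NA_integer_)
  idx[1]
}

#' Fit a gamma-variate to the first tracer passage
#'
#' Nonlinear least squares of `A (t - t0)^a exp(-(t - t0)/b)` over the
#' window from the end of the baseline to the steady-state start,
#' initialised by log-linearisation (`log C` is linear in `log(t - t0)` and
#' `t - t0` at fixed `t0`) and refined by Levenberg-Marquardt.  The fitted
#' first-passage area has the closed form `A * Gamma(a+1) * b^(a+1)`.
#'
#' @param curve concentration curve with a positive peak.
#' @param grid the matching [time_grid()].
#' @param baseline_end fit-window start, seconds.
#' @param steady_frac threshold for [steady_state_start()].
#' @return A `gamma_fit` list: `converged`, `t0`, `a`, `b`, `amplitude`,
#'   `auc_first`, `ss_index` (steady-state start), `resid_norm`.
#'   Non-convergence is reported via `converged = FALSE`, never raised.
#' @export
fit_gamma_first_passage <- function(curve, grid, baseline_end = 26,
                                    steady_frac = 0.30) {
  bad <- list(converged = FALSE, t0 = NA_real_, a = NA_real_, b = NA_real_,
              amplitude = NA_real_, auc_first = NA_real_,
              ss_index = NA_integer_, resid_norm = NA_real_)
  class(bad) <- "gamma_fit"
  hp <- max(curve)
  if (!is.finite(hp) || hp <= 0) return(bad)
  ss <- steady_state_start(curve, grid, steady_frac)
  bad$ss_index <- ss
  win <- which(grid$time >= baseline_end &
                 grid$time <= grid$time[if (is.na(ss)) grid$n else ss])
  if (length(win) < 5) return(bad)
  t <- grid$time[win]
  y <- curve[win]

  # log-linearisation init: candidate t0 just before the upslope
  pos <- y > 0.05 * hp
  if (sum(pos) < 4) return(bad)
  t0_cand <- t[which(pos)[1]] - grid$dt
  init <- tryCatch({
    yy <- y[pos & t > t0_cand]
    tt <- t[pos & t > t0_cand]
    co <- unname(stats::coef(stats::lm(log(yy) ~ log(tt - t0_cand) + I(tt - t0_cand))))
    a0 <- max(co[2], 0.2)
    b0 <- if (co[3] < 0) -1 / co[3] else 2
    list(A = exp(co[1]), t0 = t0_cand, a = a0, b = min(max(b0, 0.2), 20))
  }, error = function(e) list(A = hp / 4.5, t0 = t0_cand, a = 3, b = 1.5))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * ifelse(t > t0, (t - t0)^a * exp(-(t - t0) / b), 0),
      start = init,
      lower = c(A = 0, t0 = 0, a = 0.05, b = 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  p <- stats::coef(fit)
  out <- list(converged = TRUE, t0 = unname(p["t0"]), a = unname(p["a"]),
              b = unname(p["b"]), amplitude = unname(p["A"]),
              auc_first = unname(p["A"] * gamma(p["a"] + 1) * p["b"]^(p["a"] + 1)),
              ss_index = ss,
              resid_norm = sqrt(sum(stats::resid(fit)^2)))
  class(out) <- "gamma_fit"
  out
}

#' Partial-volume ratio filter
#'
#' For each curve, the ratio `AUC_2nd / AUC_1st` of the integrated
#' steady state (the `steady_len` samples following the steady-state start,
#' times dt) to the fitted first-passage area.  This ratio is a pure shape
#' quantity and is (near) equal for uncontaminated arterial and tissue
#' responses, but deviates for partial-volume voxels because signal-level
#' mixing is nonlinear in concentration.  Curves whose ratio falls outside
#' `mean(r) * (1 +/- pve_tol)` are excluded, as are curves with failed fits
#' or no usable steady state.  The mean is computed once over all candidate
#' curves (single pass).
#'
#' @param curves a concentration [curve_set()].
#' @param config a [filter_config()].
#' @param fits optional precomputed list of `gamma_fit`s, one per curve.
#' @return The filtered [curve_set()] with `"trace"` and `"ratios"`
#'   attributes.
#' @export
pve_ratio_filter <- function(curves, config = filter_config(), fits = NULL) {
  n <- nrow(curves$values)
  grid <- curves$grid
  if (is.null(fits)) {
    fits <- lapply(seq_len(n), function(i)
      fit_gamma_first_passage(curves$values[i, ], grid,
                              config$baseline_end, config$steady_frac))
  }
  stopifnot(length(fits) == n)
  ratios <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- fits[[i]]
    if (!isTRUE(f$converged) || !is.finite(f$auc_first) || f$auc_first <= 0)
      next
    ss <- f$ss_index
    if (is.na(ss) || ss + config$steady_len > grid$n) next
    auc2 <- sum(curves$values[i, (ss + 1):(ss + config$steady_len)]) * grid$dt
    ratios[i] <- auc2 / f$auc_first
  }
  ok <- is.finite(ratios)
  if (!any(ok)) stop("no curve yielded a usable steady-state ratio")
  mr <- mean(ratios[ok])
  keep <- ok & abs(ratios - mr) <= config$pve_tol * mr
  out <- subset_curves(curves, curves$ids[keep])
  attr(out, "trace") <- filter_trace("pve_ratio_filter", n, sum(keep),
                                     curves$ids[!keep])
  attr(out, "ratios") <- stats::setNames(ratios, curves$ids)
  attr(out, "mean_ratio") <- mr
  out
}
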