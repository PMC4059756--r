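#' Gamma-variate bolus curve
#'
#' The canonical first-passage bolus shape
#' \deqn{C(t) = (t - t_0)^a \exp(-(t - t_0)/b), \quad t > t_0,}
#' and 0 otherwise.  The function is deliberately unnormalised (no leading
#' constant): its analytic maximum is \eqn{(ab)^a e^{-a}}, which for the
#' default arterial parameters a = 3, b = 1.5 equals 4.5369.
#'
#' @param t time in seconds (vectorised).
#' @param t0 bolus arrival time in seconds.
#' @param a inflow-steepness exponent (dimensionless, > 0).
#' @param b washout time scale in seconds (> 0).
#' @return Concentration values (arbitrary units), 0 for `t <= t0`.
#' @examples
#' gamma_variate(30.5, 26, 3, 1.5)  # 4.5369, the arterial peak
#' @export
gamma_variate <- function(t, t0, a, b) {
  if (!all(is.finite(t))) stop("non-finite time values")
  stopifnot(a > 0, b > 0, t0 >= 0)
  out <- numeric(length(t))
  up <- t > t0
  out[up] <- (t[up] - t0)^a * exp(-(t[up] - t0) / b)
  out
}

#' Arterial model parameters
#'
#' Gamma-variate plus recirculation parameters describing an arterial bolus
#' passage.  Defaults are the true-AIF values: arrival at 26 s, steepness 3,
#' washout scale 1.5 s, recirculation delayed by 8 s and dispersed by an
#' exponential with a 30 s time constant.
#'
#' @param t0 bolus arrival time, s.
#' @param a inflow-steepness exponent.
#' @param b washout time scale, s.
#' @param recirc_delay recirculation delay, s.
#' @param recirc_tau recirculation exponential time constant, s.
#' @param recirc_unit_area normalise the recirculation kernel to unit area
#'   (`(1/tau) exp(-t/tau)`)?  If `FALSE` the kernel `exp(-t/tau)` is used.
#' @return An `aif_params` object (a list).
#' @export
aif_params <- function(t0 = 26, a = 3, b = 1.5, recirc_delay = 8,
                       recirc_tau = 30, recirc_unit_area = TRUE) {
  stopifnot(t0 >= 0, a > 0, b > 0, recirc_tau > 0)
  structure(list(t0 = t0, a = a, b = b, recirc_delay = recirc_delay,
                 recirc_tau = recirc_tau, recirc_unit_area = recirc_unit_area),
            class = "aif_params")
}

#' Simulated arterial input function with recirculation
#'
#' First passage modelled by [gamma_variate()]; recirculation as a copy of
#' the first passage delayed by `recirc_delay` and convolved with an
#' exponential kernel of time constant `recirc_tau` (unit area by default).
#'
#' @param grid a [time_grid()] covering the bolus arrival.
#' @param p an [aif_params()] object.
#' @return Concentration curve on the grid; non-negative, exactly zero
#'   before `t0`.
#' @export
make_true_aif <- function(grid, p = aif_params()) {
  stopifnot(inherits(grid, "time_grid"))
  if (p$t0 > grid$time[grid$n]) stop("grid does not cover bolus arrival t0")
  first <- gamma_variate(grid$time, p$t0, p$a, p$b)
  delayed <- gamma_variate(grid$time, p$t0 + p$recirc_delay, p$a, p$b)
  kern <- exp(-(grid$time - grid$start) / p$recirc_tau)
  if (p$recirc_unit_area) kern <- kern / p$recirc_tau
  first + conv_causal(delayed, kern, grid$dt)
}

#' False arterial curves
#'
#' Late/dispersed arterial look-alikes (e.g. veins, delayed branches):
#' arrival times 27-30 s crossed with recirculation delays 9-12 s in 1 s
#' increments, all other parameters as the base arterial model.
#'
#' @param grid a [time_grid()].
#' @param base an [aif_params()] giving the shared parameters.
#' @param t0_values,delay_values parameter grids for arrival and delay.
#' @return A list with `curves` (16 x n matrix) and `params` (data frame of
#'   the t0/delay combinations, in row order).
#' @export
make_false_aifs <- function(grid, base = aif_params(),
                            t0_values = 27:30, delay_values = 9:12) {
  combos <- expand.grid(recirc_delay = delay_values, t0 = t0_values)[, 2:1]
  curves <- t(vapply(seq_len(nrow(combos)), function(i) {
    p <- base
    p$t0 <- combos$t0[i]
    p$recirc_delay <- combos$recirc_delay[i]
    make_true_aif(grid, p)
  }, numeric(grid$n)))
  list(curves = curves, params = combos)
}

#' Vascular residue function
#'
#' Fraction of tracer still present in the vasculature at time t after an
#' ideal instantaneous injection; `R(0) = 1`, non-increasing, and its time
#' integral equals the mean transit time (central volume theorem).  The
#' default shape exponent 0 gives the exponential member
#' `R(t) = exp(-t/mtt)` of the gamma-variate family; positive exponents give
#' `(1 - P(shape+1, t (shape+1)/mtt))`-type more boxcar-like members via the
#' regularised upper incomplete gamma function, still integrating to `mtt`.
#'
#' @param grid a [time_grid()].
#' @param mtt mean transit time in seconds (> 0).
#' @param shape shape exponent (>= 0); 0 is exponential washout.
#' @return Dimensionless curve on the grid.
#' @export
residue_function <- function(grid, mtt, shape = 0) {
  if (!is.numeric(mtt) || mtt <= 0) stop("mtt must be > 0")
  stopifnot(shape >= 0)
  tt <- grid$time - grid$start
  if (shape == 0) {
    exp(-tt / mtt)
  } else {
    # survival function of a gamma(shape+1, scale = mtt/(shape+1)) transit
    # time distribution: mean transit time = mtt, R(0) = 1, non-increasing
    stats::pgamma(tt, shape = shape + 1, scale = mtt / (shape + 1),
                  lower.tail = FALSE)
  }
}

#' Tissue concentration by the indicator-dilution convolution
#'
#' `Ct = CBF * (Ca conv R) * dt` with `CBF = CBV/MTT` (central volume
#' theorem).  CBV is given in ml/100 g and converted to a volume fraction
#' internally; remaining proportionality constants (density, hematocrit) are
#' 1, so only relative amplitudes are meaningful.
#'
#' @param aif arterial concentration curve on `grid`.
#' @param cbv cerebral blood volume, ml/100 g.
#' @param mtt mean transit time, s.
#' @param grid a [time_grid()].
#' @param shape residue-function shape exponent, see [residue_function()].
#' @return Tissue concentration curve (non-negative, 0 at t = start).
#' @export
tissue_concentration <- function(aif, cbv, mtt, grid, shape = 0) {
  if (length(aif) != grid$n) stop("aif and grid length mismatch")
  stopifnot(cbv > 0, mtt > 0)
  cbf <- (cbv / 100) / mtt
  cbf * conv_causal(aif, residue_function(grid, mtt, shape), grid$dt)
}

#' Tissue class specification
#'
#' @param name one of `"normal_GM"`, `"path_GM"`, `"WM"` (or any label).
#' @param cbv cerebral blood volume, ml/100 g.
#' @param mtt_mean,mtt_sd mean transit time mean and jitter SD, s.
#' @param count number of voxels of this class.
#' @return A `tissue_class_spec` object.
#' @export
tissue_class_spec <- function(name, cbv, mtt_mean, mtt_sd, count) {
  stopifnot(cbv > 0, mtt_mean > 0, mtt_sd >= 0, count >= 0)
  structure(list(name = name, cbv = cbv, mtt_mean = mtt_mean,
                 mtt_sd = mtt_sd, count = as.integer(count)),
            class = "tissue_class_spec")
}

#' Default tissue population
#'
#' Normal grey matter (CBV 4 ml/100 g, MTT 4 +/- 0.33 s, 440 voxels),
#' pathological grey matter (3.3, 10 +/- 0.7, 440) and white matter
#' (2, 5.45 +/- 0.33, 600).
#'
#' @return A named list of [tissue_class_spec()] objects.
#' @export
default_tissue_classes <- function() {
  list(
    normal_GM = tissue_class_spec("normal_GM", 4,    4,    0.33, 440),
    path_GM   = tissue_class_spec("path_GM",   3.3, 10,    0.7,  440),
    WM        = tissue_class_spec("WM",        2,    5.45, 0.33, 600))
}

#' Acquisition parameters
#'
#' @param s0 baseline signal intensity, arbitrary units.
#' @param te echo time, seconds.
#' @param k_const concentration-to-relaxivity proportionality constant; `NA`
#'   means "calibrate from normal grey matter" (see [calibrate_k()]).
#' @return An `acquisition_params` object.
#' @export
acquisition_params <- function(s0 = 100, te = 0.030, k_const = NA_real_) {
  stopifnot(s0 > 0, te > 0, is.na(k_const) || k_const > 0)
  structure(list(s0 = s0, te = te, k_const = k_const),
            class = "acquisition_params")
}

#' Calibrate the signal proportionality constant
#'
#' Returns the constant k such that the mean normal-grey-matter voxel shows
#' a 40 % signal peak decrease from baseline (signal trough `0.6 * S0`),
#' i.e. `k = -log(0.6) / (TE * max(Ct_GM))` for the class at its mean MTT.
#'
#' @param grid a [time_grid()].
#' @param aif arterial concentration curve.
#' @param gm_spec a [tissue_class_spec()] for normal grey matter.
#' @param acq an [acquisition_params()].
#' @param drop fractional signal decrease to calibrate to (default 0.40).
#' @return The calibrated `k_const`.
#' @export
calibrate_k <- function(grid, aif, gm_spec = default_tissue_classes()$normal_GM,
                        acq = acquisition_params(), drop = 0.40) {
  ct <- tissue_concentration(aif, gm_spec$cbv, gm_spec$mtt_mean, grid)
  m <- max(ct)
  if (m <= 0) stop("grey-matter concentration is identically zero")
  -log(1 - drop) / (acq$te * m)
}

#' Convert concentration to MR signal
#'
#' The T2*-weighted bolus-tracking signal model
#' `S(t) = S0 * exp(-k * C(t) * TE)`.
#'
#' @param ct concentration curve (non-negative).
#' @param acq an [acquisition_params()] with a concrete `k_const`.
#' @return Signal curve, `0 < S <= S0`.
#' @export
concentration_to_signal <- function(ct, acq) {
  if (is.na(acq$k_const)) stop("k_const has not been calibrated")
  stopifnot(all(ct >= 0))
  acq$s0 * exp(-acq$k_const * ct * acq$te)
}

#' Mix an arterial and a tissue signal (partial volume)
#'
#' Linear signal-level combination `w * arterial + (1 - w) * tissue`,
#' emulating a voxel whose volume is shared between an artery and
#' surrounding tissue.
#'
#' @param arterial_signal,tissue_signal signal curves on the same grid.
#' @param w arterial volume fraction in \[0, 1\].
#' @return Mixed signal curve.
#' @export
mix_pve <- function(arterial_signal, tissue_signal, w) {
  if (!is.numeric(w) || w < 0 || w > 1) stop("w must be in [0, 1]")
  stopifnot(length(arterial_signal) == length(tissue_signal))
  w * arterial_signal + (1 - w) * tissue_signal
}

#' Noise specification
#'
#' Zero-mean Gaussian noise with `SD = S0/SNR` added to a random subset of
#' signal curves.  `magnitude = TRUE` (the default) takes the absolute value
#' after adding noise: MR images are magnitude images, so near-zero signals
#' follow a Rician rather than Gaussian law, while at `S >> SD` the two are
#' indistinguishable.
#'
#' @param snr signal-to-noise ratio `S0/SD` (typically 20, 40 or 60).
#' @param n_noisy_curves number of curves to corrupt.
#' @param magnitude take `abs()` after adding noise?
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(snr = 20, n_noisy_curves = 100, magnitude = TRUE) {
  stopifnot(snr > 0, n_noisy_curves >= 0)
  structure(list(snr = snr, n_noisy_curves = as.integer(n_noisy_curves),
                 magnitude = magnitude),
            class = "noise_spec")
}

#' Add noise to a subset of signal curves
#'
#' @param signals voxel-by-time signal matrix.
#' @param spec a [noise_spec()].
#' @param s0 baseline signal used in the SNR definition.
#' @param seed RNG seed for the curve selection and the noise draws.
#' @return A list: `signals` (noisy matrix) and `noisy_rows` (index set).
#' @export
add_noise <- function(signals, spec = noise_spec(), s0 = 100, seed = NULL) {
  nn <- spec$n_noisy_curves
  if (nn > nrow(signals)) stop("more noisy curves requested than available")
  if (!is.null(seed)) set.seed(seed)
  if (nn == 0) return(list(signals = signals, noisy_rows = integer(0)))
  rows <- sort(sample.int(nrow(signals), nn))
  noise <- matrix(stats::rnorm(nn * ncol(signals), 0, s0 / spec$snr),
                  nrow = nn)
  noisy <- signals[rows, , drop = FALSE] + noise
  if (spec$magnitude) noisy <- abs(noisy)
  signals[rows, ] <- noisy
  list(signals = signals, noisy_rows = rows)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic bolus-passage study: the time grid,
#' the arterial model, the tissue population, the acquisition and the noise
#' model.  Defaults reproduce the standard study conditions: 6 true
#' arterial, 16 false arterial, 440 normal-GM, 440 pathological-GM, 600 WM
#' and 400 partial-volume voxels on a 90 s / 1 s grid, Gaussian noise on 100
#' random curves.
#'
#' @param grid a [time_grid()].
#' @param aif an [aif_params()] for the true artery.
#' @param n_true_arterial,n_pve voxel counts for the two arterial-content
#'   classes (false-arterial count follows from `false_t0`/`false_delay`).
#' @param false_t0,false_delay parameter grids for the false arteries.
#' @param tissues list of [tissue_class_spec()]s.
#' @param acq an [acquisition_params()].
#' @param noise a [noise_spec()].
#' @param mtt_jitter `"gaussian"` (mean +/- SD, truncated at 0.5 s) or
#'   `"uniform"` (mean +/- SD as hard bounds).
#' @return A `sim_config` object.
#' @export
sim_config <- function(grid = time_grid(),
                       aif = aif_params(),
                       n_true_arterial = 6,
                       false_t0 = 27:30, false_delay = 9:12,
                       tissues = default_tissue_classes(),
                       n_pve = 400,
                       acq = acquisition_params(),
                       noise = noise_spec(),
                       mtt_jitter = c("gaussian", "uniform")) {
  structure(list(grid = grid, aif = aif,
                 n_true_arterial = as.integer(n_true_arterial),
                 false_t0 = false_t0, false_delay = false_delay,
                 tissues = tissues, n_pve = as.integer(n_pve),
                 acq = acq, noise = noise,
                 mtt_jitter = match.arg(mtt_jitter)),
            class = "sim_config")
}

draw_mtt <- function(spec, n, how) {
  if (how == "uniform") {
    stats::runif(n, spec$mtt_mean - spec$mtt_sd, spec$mtt_mean + spec$mtt_sd)
  } else {
    pmax(0.5, stats::rnorm(n, spec$mtt_mean, spec$mtt_sd))
  }
}

#' Build a synthetic bolus-passage dataset
#'
#' Generates the full voxel population through the chain
#' arterial model -> residue-function convolution -> signal model -> partial
#' volume mixing -> noise, with per-voxel ground-truth class labels and the
#' noise-free true arterial concentration curve.
#'
#' One master seed drives four independent sub-streams (MTT jitter, PVE
#' mixing, noisy-curve selection + noise, and nothing else), so e.g. the
#' tissue population is bit-identical across noise settings at a fixed seed.
#'
#' @param config a [sim_config()].
#' @param seed master RNG seed.
#' @return An `aif_dataset`: `signals` (a [curve_set()]), `labels` (data
#'   frame with `id`, `class`, `mix_weight`), `true_aif`, `k_const`, `acq`,
#'   `config`, `seed`, and `noisy_rows`.
#' @examples
#' ds <- build_dataset(seed = 1)
#' nrow(ds$signals$values)   # 1902
#' table(ds$labels$class)
#' @export
build_dataset <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  subseeds <- sample.int(2^31 - 2, 4)
  grid <- config$grid
  acq <- config$acq

  true_aif <- make_true_aif(grid, config$aif)
  if (is.na(acq$k_const))
    acq$k_const <- calibrate_k(grid, true_aif, config$tissues$normal_GM, acq)

  s_true <- concentration_to_signal(true_aif, acq)
  false_set <- make_false_aifs(grid, config$aif, config$false_t0, config$false_delay)

  n_false <- nrow(false_set$curves)
  n_tis <- vapply(config$tissues, `[[`, integer(1), "count")
  n_total <- config$n_true_arterial + n_false + sum(n_tis) + config$n_pve

  signals <- matrix(0, n_total, grid$n)
  class <- character(n_total)
  mixw <- rep(NA_real_, n_total)

  r <- 0
  for (i in seq_len(config$n_true_arterial)) {
    r <- r + 1; signals[r, ] <- s_true; class[r] <- "true_arterial"
  }
  for (i in seq_len(n_false)) {
    r <- r + 1
    signals[r, ] <- concentration_to_signal(false_set$curves[i, ], acq)
    class[r] <- "false_arterial"
  }

  # tissue voxels: MTT jitter sub-stream
  set.seed(subseeds[1])
  tissue_pool <- list()   # per-class signal banks reused for PVE mixing
  for (spec in config$tissues) {
    if (spec$count == 0) next
    mtts <- draw_mtt(spec, spec$count, config$mtt_jitter)
    block <- t(vapply(mtts, function(m) {
      concentration_to_signal(
        tissue_concentration(true_aif, spec$cbv, m, grid), acq)
    }, numeric(grid$n)))
    idx <- r + seq_len(spec$count)
    signals[idx, ] <- block
    class[idx] <- spec$name
    r <- r + spec$count
    tissue_pool[[spec$name]] <- spec
  }

  # partial-volume voxels: mixing sub-stream
  set.seed(subseeds[2])
  if (config$n_pve > 0) {
    tnames <- names(tissue_pool)
    for (i in seq_len(config$n_pve)) {
      r <- r + 1
      w <- stats::runif(1)
      spec <- tissue_pool[[sample(length(tnames), 1)]]
      mtt <- draw_mtt(spec, 1, config$mtt_jitter)
      s_tis <- concentration_to_signal(
        tissue_concentration(true_aif, spec$cbv, mtt, grid), acq)
      signals[r, ] <- mix_pve(s_true, s_tis, w)
      class[r] <- "pve_mix"
      mixw[r] <- w
    }
  }

  noised <- add_noise(signals, config$noise, s0 = acq$s0, seed = subseeds[3])

  ids <- sprintf("v%04d", seq_len(n_total))
  structure(list(
    signals = curve_set(noised$signals, grid, ids = ids, kind = "signal"),
    labels = data.frame(id = ids, class = class, mix_weight = mixw,
                        stringsAsFactors = FALSE),
    true_aif = true_aif,
    k_const = acq$k_const,
    acq = acq,
    config = config,
    seed = seed,
    noisy_rows = noised$noisy_rows), class = "aif_dataset")
}

#' @export
print.aif_dataset <- function(x, ...) {
  cat(sprintf("<aif_dataset> %d voxels x %d time points (seed %s)\n",
              nrow(x$signals$values), x$signals$grid$n, format(x$seed)))
  print(table(x$labels$class))
  invisible(x)
}
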