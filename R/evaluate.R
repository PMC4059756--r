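#' Partial-volume level of a selection
#'
#' Fraction of curves in the selected (putatively arterial) set whose
#' ground-truth class is not `true_arterial`.
#'
#' @param selected_ids ids of the selected curves.
#' @param labels the `labels` data frame of an `aif_dataset`.
#' @return A fraction in \[0, 1\].
#' @export
pve_level <- function(selected_ids, labels) {
  if (length(selected_ids) == 0) stop("empty selection")
  cls <- labels$class[match(selected_ids, labels$id)]
  if (anyNA(cls)) stop("unknown ids in selection")
  mean(cls != "true_arterial")
}

#' RMSE between a detected and the true AIF
#'
#' `sqrt(mean((est - true)^2))` over the full scan.
#'
#' @param estimated,true concentration curves on the same grid.
#' @return The root-mean-square error (>= 0).
#' @export
aif_rmse <- function(estimated, true) {
  if (length(estimated) != length(true)) stop("grid mismatch")
  sqrt(mean((estimated - true)^2))
}

#' Across-run robustness of repeated AIF detections
#'
#' The variance of the detected AIF curves across repeated runs: the mean
#' (over runs and time points) squared deviation from the across-run mean
#' curve.  Exactly zero iff every run produced the same curve — the
#' signature of a deterministic detector.
#'
#' @param aifs runs-by-time matrix of detected AIF curves (N >= 2 rows).
#' @param unbiased divide by `(N-1)*M` (default) or `N*M`.
#' @return A `robustness_result` list: `robustness`, `n_runs`,
#'   `n_timepoints`.
#' @export
aif_robustness <- function(aifs, unbiased = TRUE) {
  aifs <- as.matrix(aifs)
  n <- nrow(aifs)
  m <- ncol(aifs)
  if (n < 2) stop("need at least 2 runs (variance undefined)")
  dev <- sweep(aifs, 2, colMeans(aifs))
  denom <- if (unbiased) (n - 1) * m else n * m
  structure(list(robustness = sum(dev^2) / denom,
                 n_runs = n, n_timepoints = m),
            class = "robustness_result")
}

#' Run the AIF detection pipeline on a curve set
#'
#' In `"simulate"` mode the signal curves are converted to concentration
#' and clustered directly; in `"clinical"` mode the candidate filter chain
#' (area filter, roughness filter, partial-volume ratio filter) is applied
#' between conversion and clustering.  The arterial cluster is selected by
#' the maximal M statistic and its mean curve returned as the AIF.
#'
#' @param curves a signal [curve_set()] (or an `aif_dataset`, whose signal
#'   curves and calibrated `k_const` are then used).
#' @param method `"ah"`, `"kmeans"` or `"fcm"`.
#' @param k number of clusters.
#' @param mode `"simulate"` or `"clinical"`.
#' @param te echo time, seconds.
#' @param k_const conversion constant, see [signal_to_concentration()].
#' @param baseline_end pre-contrast window end, seconds.
#' @param filters a [filter_config()] (clinical mode).
#' @param seed RNG seed for the iterative clustering methods (ignored by
#'   the deterministic AH method).
#' @param distances optional precomputed distance matrix (AH only); for
#'   honest repeated-run timing leave it `NULL`.
#' @return A list: `aif`, `selected_ids`, `cluster` (selected id),
#'   `metrics`, `assignment`, `concentration` (the clustered curves) and
#'   `traces` (filter traces, clinical mode).
#' @export
detect_aif <- function(curves, method = c("ah", "kmeans", "fcm"), k = 5,
                       mode = c("simulate", "clinical"),
                       te = 0.030, k_const = 1, baseline_end = 26,
                       filters = filter_config(), seed = NULL,
                       distances = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (inherits(curves, "aif_dataset")) {
    if (missing(k_const)) k_const <- curves$k_const
    if (missing(te)) te <- curves$acq$te
    curves <- curves$signals
  }
  stopifnot(inherits(curves, "curve_set"))

  conc <- signal_to_concentration(curves, te, baseline_end, k_const)
  traces <- list(attr(conc, "trace"))
  if (mode == "clinical") {
    conc <- auc_filter(conc, filters$p_auc)
    traces <- c(traces, list(attr(conc, "trace")))
    conc <- roughness_filter(conc, filters$p_rough)
    traces <- c(traces, list(attr(conc, "trace")))
    conc <- pve_ratio_filter(conc, filters)
    traces <- c(traces, list(attr(conc, "trace")))
  }

  assignment <- switch(method,
    ah = ah_cluster(conc, k, distances = distances),
    kmeans = kmeans_cluster(conc, k, seed = seed),
    fcm = fcm_cluster(conc, k, seed = seed))

  sel <- select_aif(assignment, conc$grid)
  list(aif = sel$aif, selected_ids = sel$selected_ids,
       cluster = sel$cluster, metrics = sel$metrics,
       assignment = assignment, concentration = conc, traces = traces)
}

#' Compare clustering methods on simulated data
#'
#' For every SNR and clustering method: build a synthetic dataset, convert,
#' cluster, select, and score against the known truth.  Emits one row per
#' (snr, method) plus a reference row for the true AIF itself (PVE 0,
#' RMSE 0 by construction).
#'
#' @param snr SNR levels to simulate.
#' @param methods clustering methods to compare.
#' @param seed master seed; dataset and method seeds derive from it.
#' @param config base [sim_config()] (its noise SNR is overridden).
#' @param k number of clusters.
#' @return A data frame with columns `snr`, `method`, `pve`, `h_p`, `t_p`,
#'   `fwhm`, `auc`, `rmse`, `m`, `n_selected`.
#' @export
compare_methods <- function(snr = c(20, 40, 60),
                            methods = c("ah", "kmeans", "fcm"),
                            seed = 1, config = sim_config(), k = 5) {
  set.seed(seed)
  method_seeds <- sample.int(2^31 - 2, length(snr) * length(methods))
  rows <- list()
  si <- 0
  for (s in snr) {
    cfg <- config
    cfg$noise$snr <- s
    ds <- build_dataset(cfg, seed = seed)
    for (mth in methods) {
      si <- si + 1
      det <- detect_aif(ds, method = mth, k = k, mode = "simulate",
                        seed = method_seeds[si])
      sm <- shape_metrics(det$aif, ds$signals$grid)
      rows[[length(rows) + 1]] <- data.frame(
        snr = s, method = mth,
        pve = pve_level(det$selected_ids, ds$labels),
        h_p = sm$h_p, t_p = sm$t_p, fwhm = sm$fwhm, auc = sm$auc,
        rmse = aif_rmse(det$aif, ds$true_aif), m = sm$m,
        n_selected = length(det$selected_ids))
    }
  }
  cfg0 <- config
  grid <- cfg0$grid
  true_aif <- make_true_aif(grid, cfg0$aif)
  smt <- shape_metrics(true_aif, grid)
  rows[[length(rows) + 1]] <- data.frame(
    snr = 0, method = "true", pve = 0, h_p = smt$h_p, t_p = smt$t_p,
    fwhm = smt$fwhm, auc = smt$auc, rmse = 0, m = smt$m, n_selected = NA)
  do.call(rbind, rows)
}

#' Repeated-detection reproducibility experiment
#'
#' Runs the detector `n_runs` times in succession on the identical curve
#' set — with a fresh seed per run for the iterative methods, and no seed
#' at all for the deterministic AH method — and quantifies the across-run
#' variance of the detected AIF curves.
#'
#' @param curves a signal [curve_set()] or `aif_dataset`.
#' @param method clustering method.
#' @param n_runs number of repeated detections (>= 2).
#' @param seed master seed from which the per-run seeds derive.
#' @param ... passed to [detect_aif()].
#' @return A `robustness_result` with the stacked AIF matrix in `$aifs`.
#' @export
reproducibility_experiment <- function(curves, method = "ah", n_runs = 100,
                                       seed = 1, ...) {
  if (n_runs < 2) stop("need at least 2 runs (variance undefined)")
  set.seed(seed)
  run_seeds <- sample.int(2^31 - 2, n_runs)
  aifs <- NULL
  for (i in seq_len(n_runs)) {
    det <- detect_aif(curves, method = method, seed = run_seeds[i], ...)
    if (is.null(aifs)) aifs <- matrix(NA_real_, n_runs, length(det$aif))
    aifs[i, ] <- det$aif
  }
  out <- aif_robustness(aifs)
  out$method <- method
  out$aifs <- aifs
  out
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("<robustness> %.6f over %d runs x %d time points\n",
              x$robustness, x$n_runs, x$n_timepoints))
  invisible(x)
}
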