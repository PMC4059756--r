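#' Write a synthetic dataset to disk
#'
#' Curves as CSV (one row per voxel: id, class label, mixing weight, then
#' the per-timepoint signal values) and a JSON sidecar with the seed, the
#' calibrated constant and a config snapshot, so a stored run is fully
#' reproducible.
#'
#' @param dataset an `aif_dataset`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(id = dataset$labels$id,
                   class = dataset$labels$class,
                   mix_weight = dataset$labels$mix_weight,
                   dataset$signals$values, check.names = FALSE)
  colnames(df) <- c("id", "class", "mix_weight",
                    sprintf("t%g", dataset$signals$grid$time))
  utils::write.csv(df, file.path(dir, "curves.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = dataset$signals$grid$time,
                              true_aif = dataset$true_aif),
                   file.path(dir, "true_aif.csv"), row.names = FALSE)
  meta <- list(seed = dataset$seed, k_const = dataset$k_const,
               s0 = dataset$acq$s0, te = dataset$acq$te,
               snr = dataset$config$noise$snr,
               n_noisy = dataset$config$noise$n_noisy_curves,
               n_voxels = nrow(dataset$signals$values),
               dt = dataset$signals$grid$dt,
               duration = dataset$signals$grid$n * dataset$signals$grid$dt)
  jsonlite::write_json(meta, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a curve set as a 4D NIfTI phantom
#'
#' Tiles the voxels row-major into a single slice of size
#' `ceiling(sqrt(N)) x ceiling(N/side)` and stacks the time points along
#' the 4th dimension; unused slots are zero-filled.  The voxel order is
#' recoverable: in-slice position (row, col) (0-based) maps to curve
#' `row * ncol + col`.
#'
#' @param curves a [curve_set()] (or an `aif_dataset`'s `signals`).
#' @param path output `.nii` / `.nii.gz` path.
#' @return The layout as a list (`nrow`, `ncol`, `n_curves`), invisibly.
#' @export
write_phantom_nifti <- function(curves, path) {
  if (inherits(curves, "aif_dataset")) curves <- curves$signals
  stopifnot(inherits(curves, "curve_set"))
  n <- nrow(curves$values)
  nt <- curves$grid$n
  side <- ceiling(sqrt(n))
  nr <- side
  nc <- ceiling(n / side)
  arr <- array(0, dim = c(nr, nc, 1, nt))
  for (i in seq_len(n)) {
    r <- (i - 1) %/% nc + 1
    c <- (i - 1) %% nc + 1
    arr[r, c, 1, ] <- curves$values[i, ]
  }
  img <- RNifti::asNifti(arr)
  img$pixdim[5] <- curves$grid$dt
  RNifti::writeNifti(img, path)
  invisible(list(nrow = nr, ncol = nc, n_curves = n))
}

#' Extract per-voxel curves from a 4D perfusion NIfTI
#'
#' Reads one slice of a 4D series (time along the 4th dimension) and
#' returns one signal curve per in-slice voxel.  Voxel ids encode the
#' 0-based (row, col) position.  The first `n_discard` volumes can be
#' dropped (scanners need a few volumes to reach a steady magnetisation
#' state); time 0 is assigned to the first retained volume.
#'
#' @param path path to a 4D NIfTI file.
#' @param slice_index 1-based slice (3rd dimension) index.
#' @param dt temporal resolution in seconds (defaults to the file's
#'   `pixdim[5]` when positive).
#' @param n_discard number of leading volumes to drop (default 2, the
#'   usual pre-steady-state volumes; pass 0 for simulator phantoms).
#' @return A signal [curve_set()].
#' @export
read_perfusion_nifti <- function(path, slice_index, dt = NULL, n_discard = 2) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("input must be a 4D time series")
  if (slice_index < 1 || slice_index > d[3]) stop("slice index out of range")
  if (n_discard < 0 || n_discard >= d[4]) stop("invalid n_discard")
  if (is.null(dt)) {
    pd <- attr(img, "pixdim")
    dt <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  }
  vols <- (n_discard + 1):d[4]
  nr <- d[1]; nc <- d[2]
  vals <- matrix(0, nr * nc, length(vols))
  ids <- character(nr * nc)
  i <- 0
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      i <- i + 1
      vals[i, ] <- img[r, c, slice_index, vols]
      ids[i] <- sprintf("r%03d_c%03d", r - 1, c - 1)
    }
  }
  grid <- time_grid(duration = length(vols) * dt, dt = dt, start = 0)
  curve_set(vals, grid, ids = ids, kind = "signal")
}

#' Read / write a pipeline configuration
#'
#' Round-trippable run configuration (JSON or YAML by file extension)
#' covering the simulation, filtering and clustering parameters plus the
#' master seed.
#'
#' @param config a named list of parameters.
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return `read_pipeline_config` returns the named list.
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
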