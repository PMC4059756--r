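#' A set of voxel curves on a common time grid
#'
#' The central container of the pipeline: a voxel-by-time matrix of signal
#' or concentration values with stable voxel identifiers.
#'
#' @param values numeric matrix, one row per voxel.
#' @param grid a [time_grid()] whose length matches `ncol(values)`.
#' @param ids character vector of unique voxel identifiers (default
#'   `"v0001"`, ...).
#' @param kind `"signal"` (raw MR intensities) or `"concentration"`.
#' @return A `curve_set` object.
#' @export
curve_set <- function(values, grid, ids = NULL, kind = c("signal", "concentration")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (!inherits(grid, "time_grid")) stop("grid must be a time_grid")
  if (ncol(values) != grid$n) stop("ncol(values) must equal grid$n")
  if (is.null(ids)) ids <- sprintf("v%04d", seq_len(nrow(values)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("voxel ids must be unique")
  if (length(ids) != nrow(values)) stop("one id per row required")
  if (!all(is.finite(values))) stop("curve values must be finite")
  rownames(values) <- ids
  structure(list(ids = ids, grid = grid, values = values, kind = kind),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set> %d %s curves x %d time points (dt = %g s)\n",
              nrow(x$values), x$kind, x$grid$n, x$grid$dt))
  invisible(x)
}

#' @export
dim.curve_set <- function(x) dim(x$values)

#' @export
as.matrix.curve_set <- function(x, ...) x$values

subset_curves <- function(curves, keep_ids) {
  keep_ids <- intersect(curves$ids, keep_ids)  # preserve original order
  curve_set(curves$values[keep_ids, , drop = FALSE], curves$grid,
            ids = keep_ids, kind = curves$kind)
}

#' Write / read a curve set as CSV
#'
#' One row per voxel: `id`, then one column per time point (`t0`, `t1`, ...,
#' named by sample time).  Plain UTF-8, '.' decimal separator.
#'
#' @param curves a [curve_set()].
#' @param path output CSV path.
#' @return `write_curves` returns `path` invisibly; `read_curves` returns a
#'   [curve_set()].
#' @export
write_curves <- function(curves, path) {
  df <- data.frame(id = curves$ids, curves$values, check.names = FALSE)
  colnames(df) <- c("id", sprintf("t%g", curves$grid$time))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @param kind curve kind to stamp on the result.
#' @param dt sampling interval of the stored grid.
#' @export
read_curves <- function(path, kind = c("signal", "concentration"), dt = 1) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE)
  # time-point columns are named t<seconds>; extra metadata columns
  # (class, mix_weight, ...) are ignored
  tc <- grepl("^t[0-9.]+$", colnames(df))
  if (!any(tc)) stop("no time-point columns (t<seconds>) found")
  vals <- as.matrix(df[, tc, drop = FALSE])
  tcols <- as.numeric(sub("^t", "", colnames(vals)))
  grid <- time_grid(duration = ncol(vals) * dt, dt = dt, start = tcols[1])
  curve_set(vals, grid, ids = df$id, kind = kind)
}
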