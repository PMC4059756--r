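#' Euclidean distances between curves
#'
#' Pairwise Euclidean distance over whole time courses.
#'
#' @param curves a [curve_set()] or a numeric matrix (rows = curves).
#' @return A symmetric, zero-diagonal distance matrix.
#' @export
pairwise_distances <- function(curves) {
  m <- if (inherits(curves, "curve_set")) curves$values else as.matrix(curves)
  if (nrow(m) < 2) stop("need at least 2 curves")
  if (anyNA(m)) stop("NaN/NA in input curves")
  as.matrix(stats::dist(m, method = "euclidean"))
}

new_assignment <- function(labels, k, values, ids, method,
                           n_iter = NA_integer_, seed = NULL, merges = NULL,
                           membership = NULL) {
  names(labels) <- ids
  means <- t(vapply(seq_len(k), function(j)
    colMeans(values[labels == j, , drop = FALSE]), numeric(ncol(values))))
  structure(list(labels = labels, k = k, means = means, method = method,
                 n_iter = n_iter, seed = seed, merges = merges,
                 membership = membership),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> method = %s, k = %d\n", x$method, x$k))
  print(table(x$labels))
  invisible(x)
}

#' Agglomerative hierarchical clustering (average linkage)
#'
#' The deterministic clustering at the heart of the detector.  Every curve
#' starts as its own cluster; the closest pair of clusters (shortest
#' linkage distance) is merged repeatedly until `k` clusters remain.  The
#' inter-cluster distance is the average of all cross-pair Euclidean
#' distances; internally this is maintained by Lance-Williams weighted-mean
#' updates, which are algebraically identical to recomputing the cross-pair
#' average at every step.  Ties in the minimal distance break towards the
#' lexicographically smallest pair of cluster ids (a cluster is identified
#' by the smallest original row index of its members).  There is no random
#' element: repeated runs on the same input give identical partitions.
#'
#' @param curves a [curve_set()] or numeric matrix.
#' @param k number of clusters (default 5).
#' @param distances optional precomputed matrix from [pairwise_distances()].
#' @param linkage `"average"` (the tuned default), `"single"` or
#'   `"complete"`; the alternatives are provided for completeness only.
#' @return A `cluster_assignment` with a `merges` data frame (`step`,
#'   `id1`, `id2`, `distance`; for average linkage the distances are
#'   non-decreasing).
#' @export
ah_cluster <- function(curves, k = 5, distances = NULL,
                       linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  m <- if (inherits(curves, "curve_set")) curves$values else as.matrix(curves)
  ids <- if (inherits(curves, "curve_set")) curves$ids else
    (rownames(m) %||% as.character(seq_len(nrow(m))))
  n <- nrow(m)
  if (n < k) stop("fewer curves than clusters")
  if (is.null(distances)) distances <- pairwise_distances(m)
  lk <- match(linkage, c("average", "single", "complete")) - 1L
  res <- .ah_linkage_cpp(distances, as.integer(k), lk)
  merges <- data.frame(step = seq_along(res$merge_dist),
                       id1 = res$merge_id1, id2 = res$merge_id2,
                       distance = res$merge_dist)
  new_assignment(res$labels, k, m, ids, "ah", merges = merges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sample_distinct_rows <- function(m, k) {
  ord <- sample.int(nrow(m))
  picked <- integer(0)
  for (i in ord) {
    if (!any(vapply(picked, function(p) identical(m[p, ], m[i, ]), logical(1))))
      picked <- c(picked, i)
    if (length(picked) == k) break
  }
  if (length(picked) < k) stop("fewer than k distinct curves")
  picked
}

#' k-means clustering of curves
#'
#' Lloyd iterations started from `k` distinct curves sampled without
#' replacement (seeded).  Should an iteration empty a cluster, the offending
#' center is re-seeded with the curve farthest from all current centers and
#' the run restarted.  The within-cluster sum of squares is non-increasing
#' across iterations, but the final partition depends on the initial
#' centers: different seeds can converge to different answers.
#'
#' @param curves a [curve_set()] or numeric matrix.
#' @param k number of clusters.
#' @param seed RNG seed for the initial centers.
#' @param max_iter iteration cap.
#' @return A `cluster_assignment` (with `tot_withinss` attribute).
#' @export
kmeans_cluster <- function(curves, k = 5, seed = NULL, max_iter = 300) {
  m <- if (inherits(curves, "curve_set")) curves$values else as.matrix(curves)
  ids <- if (inherits(curves, "curve_set")) curves$ids else
    (rownames(m) %||% as.character(seq_len(nrow(m))))
  if (nrow(m) < k) stop("fewer curves than clusters")
  if (!is.null(seed)) set.seed(seed)
  centers <- m[sample_distinct_rows(m, k), , drop = FALSE]
  fit <- NULL
  for (attempt in 1:10) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = centers,
                                     iter.max = max_iter,
                                     algorithm = "Lloyd")),
      error = function(e) e)
    if (!inherits(fit, "error")) break
    # empty cluster: re-seed one center with the farthest curve
    dmin <- apply(m, 1, function(row)
      min(sqrt(colSums((t(centers) - row)^2))))
    centers[which.min(stats::dist(centers))[1] %% k + 1, ] <- m[which.max(dmin), ]
  }
  if (inherits(fit, "error")) stop(fit)
  out <- new_assignment(fit$cluster, k, m, ids, "kmeans",
                        n_iter = fit$iter, seed = seed)
  attr(out, "tot_withinss") <- fit$tot.withinss
  out
}

#' Fuzzy c-means clustering of curves
#'
#' Standard alternating membership/center updates with fuzziness exponent
#' `m` (default 2); the membership matrix is row-stochastic and hard labels
#' take the maximal membership.  Initialisation is random (seeded), so like
#' k-means the result is seed-dependent.
#'
#' @param curves a [curve_set()] or numeric matrix.
#' @param k number of clusters.
#' @param m fuzziness exponent (> 1).
#' @param seed RNG seed.
#' @param max_iter iteration cap.
#' @return A `cluster_assignment` with a `membership` matrix.
#' @export
fcm_cluster <- function(curves, k = 5, m = 2, seed = NULL, max_iter = 300) {
  x <- if (inherits(curves, "curve_set")) curves$values else as.matrix(curves)
  ids <- if (inherits(curves, "curve_set")) curves$ids else
    (rownames(x) %||% as.character(seq_len(nrow(x))))
  if (nrow(x) < k) stop("fewer curves than clusters")
  stopifnot(m > 1)
  if (!is.null(seed)) set.seed(seed)
  fit <- e1071::cmeans(x, centers = k, m = m, iter.max = max_iter)
  out <- new_assignment(as.integer(fit$cluster), k, x, ids, "fcm",
                        n_iter = fit$iter, seed = seed,
                        membership = fit$membership)
  out
}
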