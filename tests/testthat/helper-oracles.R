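# Literal 4-step agglomerative average-linkage clustering: every item its
# own cluster; repeatedly find the closest pair (mean over all cross-pair
# Euclidean distances, recomputed from scratch) and merge, ties to the
# lexicographically smallest pair of cluster ids (smallest member index).
# Used as an independent oracle for the Lance-Williams implementation.
naive_average_linkage <- function(m, k) {
  n <- nrow(m)
  d0 <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))          # member indices
  merges <- NULL
  while (length(clusters) > k) {
    # scan in ascending cluster-id order so a strict < tie-breaks to the
    # lexicographically smallest (id_i, id_j) pair
    clusters <- clusters[order(vapply(clusters, min, integer(1)))]
    ids <- vapply(clusters, min, integer(1))
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dv <- mean(d0[clusters[[i]], clusters[[j]]])
        if (dv < best) { best <- dv; bi <- i; bj <- j }
      }
    }
    merges <- rbind(merges,
                    data.frame(id1 = ids[bi], id2 = ids[bj], distance = best))
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters[[bj]] <- NULL
  }
  clusters <- clusters[order(vapply(clusters, min, integer(1)))]
  labels <- integer(n)
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  list(labels = labels, merges = merges)
}

# Three well-separated groups of curves for clustering fixtures
make_group_curves <- function(n_per = 10, n_t = 30, centers = c(0, 5, 10),
                              sd = 0.1, seed = 42) {
  set.seed(seed)
  m <- do.call(rbind, lapply(centers, function(ce)
    matrix(ce + rnorm(n_per * n_t, 0, sd), n_per, n_t)))
  list(values = m,
       group = rep(seq_along(centers), each = n_per))
}

# A small, fast synthetic dataset configuration (reduced voxel counts)
small_sim_config <- function(snr = 20, n_noisy = 10) {
  tis <- list(
    normal_GM = tissue_class_spec("normal_GM", 4, 4, 0.33, 30),
    path_GM   = tissue_class_spec("path_GM", 3.3, 10, 0.7, 30),
    WM        = tissue_class_spec("WM", 2, 5.45, 0.33, 40))
  sim_config(tissues = tis, n_pve = 30,
             noise = noise_spec(snr = snr, n_noisy_curves = n_noisy))
}
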