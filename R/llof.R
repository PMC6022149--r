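#' LLOF filtering parameters
#'
#' @param k_neighbors number of same-cluster nearest neighbors used for
#'   k-distance and reachability (default 20, the upper end of the usual
#'   LOF working range).
#' @param eps1 outlier-score threshold; samples scoring above it are
#'   removed (default 1.5, comfortably above the ~1 score of points
#'   inside a tight cluster).
#' @return object of class `llof_params`.
#' @export
llof_params <- function(k_neighbors = 20, eps1 = 1.5) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (!is.finite(eps1) && !identical(eps1, Inf)) stop("eps1 must be > 0")
  if (eps1 <= 0) stop("eps1 must be > 0")
  structure(list(k_neighbors = as.integer(k_neighbors), eps1 = eps1),
            class = "llof_params")
}

#' Distance to the k-th nearest same-cluster neighbor
#'
#' @param x the query feature vector.
#' @param cluster matrix of the other members of the query's labeled
#'   cluster (the query itself excluded).
#' @param k neighbor rank.
#' @return Euclidean distance to the k-th nearest row of `cluster`.
#' @export
knn_distance_in_cluster <- function(x, cluster, k) {
  cluster <- as.matrix(cluster)
  if (nrow(cluster) < k)
    stop("cluster has only ", nrow(cluster), " other member(s); needs >= ",
         k, " - skip LLOF filtering for this cluster")
  d <- sqrt(colSums((t(cluster) - x)^2))
  sort(d, partial = k)[k]
}

#' Reachability distance between two samples
#'
#' `max(kdist_first, d(first, second))`: the true pairwise distance,
#' floored at the first sample's k-distance inside its own cluster. The
#' floor damps the statistical fluctuation of distances between close
#' records. The local density of a point C averages this quantity with
#' each neighbor D as the *first* argument (the neighbor's k-distance is
#' the floor), the standard LOF construction.
#'
#' @param x,y the two feature vectors (reachability is directional:
#'   `x`'s k-distance is the floor).
#' @param cluster matrix of `x`'s same-cluster companions, `x` excluded.
#' @param k neighbor rank for the k-distance.
#' @return the reachability distance.
#' @export
reachability_distance <- function(x, y, cluster, k) {
  max(knn_distance_in_cluster(x, cluster, k),
      sqrt(sum((x - y)^2)))
}

# Per-cluster LOF, vectorized over the whole cluster. D is the full
# symmetric distance matrix of the cluster. Returns one score per row.
# Neighborhoods include all points tied at the k-th distance, so they can
# exceed k. Degenerate 0/0 densities (duplicate points) score 1.
lof_scores_cluster <- function(Xc, k) {
  n <- nrow(Xc)
  D <- as.matrix(stats::dist(Xc))
  kdist <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    kd <- sort(di, partial = k)[k]
    kdist[i] <- kd
    nbrs[[i]] <- setdiff(which(D[i, ] <= kd), i)
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    reach <- pmax(kdist[nbrs[[i]]], D[i, nbrs[[i]]])
    s <- sum(reach)
    lrd[i] <- if (s == 0) Inf else length(nbrs[[i]]) / s
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    r <- lrd[nbrs[[i]]] / lrd[i]
    r[is.nan(r)] <- 1  # Inf/Inf: duplicates on both sides
    scores[i] <- mean(r)
  }
  scores[is.nan(scores)] <- 1
  scores
}

#' Label-based local outlier factor scores
#'
#' LOF computed with the neighbor search restricted to each sample's own
#' labeled cluster: the score of C is the mean ratio of its neighbors'
#' local reachability densities to C's own. Scores near 1 mean C is as
#' dense as its neighborhood; scores well above 1 flag annotation errors
#' and transition windows. Duplicate-point degeneracies (0/0) score 1,
#' the non-outlier value.
#'
#' @param X feature matrix (rows = samples).
#' @param labels cluster/activity label per row.
#' @param params an [llof_params()] object.
#' @return numeric vector of LLOF scores, one per row of `X`; `NA` for
#'   samples in clusters too small to score (fewer than `k_neighbors + 1`
#'   members), which are reported via a warning.
#' @export
llof_score <- function(X, labels, params = llof_params()) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(inherits(params, "llof_params"), nrow(X) == length(labels))
  k <- params$k_neighbors
  scores <- rep(NA_real_, nrow(X))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k + 1L) {
      warning("cluster '", cl, "' has ", length(idx),
              " member(s) (< k+1 = ", k + 1L,
              "); left unscored and unfiltered")
      next
    }
    scores[idx] <- lof_scores_cluster(X[idx, , drop = FALSE], k)
  }
  scores
}

#' Remove low-confidence samples by LLOF threshold
#'
#' Single-pass filtering: scores are computed once against the full
#' annotated set and every sample with `LLOF > eps1` is dropped. Clusters
#' too small to score pass through unfiltered (with a warning from the
#' scorer).
#'
#' @param X annotated feature matrix.
#' @param labels cluster label per row.
#' @param params an [llof_params()] object.
#' @return list with `kept` (feature matrix), `kept_labels`,
#'   `kept_index` (row indices into `X`), `removed_index`, and `scores`
#'   (full score vector, `NA` for unscored clusters).
#' @export
filter_outliers <- function(X, labels, params = llof_params()) {
  X <- as.matrix(X)
  scores <- llof_score(X, labels, params)
  drop <- !is.na(scores) & scores > params$eps1
  list(kept = X[!drop, , drop = FALSE],
       kept_labels = as.character(labels)[!drop],
       kept_index = which(!drop),
       removed_index = which(drop),
       scores = scores)
}
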