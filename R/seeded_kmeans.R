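#' Labeled seed centroids from a pre-collected dataset
#'
#' The initial K-Means centers are not random: they are the per-class mean
#' feature vectors of a dataset labeled in advance (typically pooled from
#' other users). Because activity data from different people are similar
#' in structure, these centers start close to the new user's optimum and
#' the converged clusters inherit the seed labels — this is what turns
#' plain clustering into automatic annotation.
#'
#' @param features numeric matrix of pre-labeled feature vectors
#'   (rows = windows, 13 columns), on the same normalized scale as the
#'   data that will be clustered.
#' @param labels character vector of class labels, one per row; all of
#'   `LIA`, `MIA`, `VIA` must be present.
#' @return object of class `seeded_centroids`: a K-by-13 matrix with
#'   class labels as row names (K = 3).
#' @export
seed_centroids <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stop("features and labels lengths differ")
  missing <- setdiff(ACTIVITY_CLASSES, unique(labels))
  if (length(missing))
    stop("pre-labeled dataset is missing class(es): ",
         paste(missing, collapse = ", "))
  centers <- t(vapply(ACTIVITY_CLASSES, function(cl)
    colMeans(features[labels == cl, , drop = FALSE]),
    numeric(ncol(features))))
  rownames(centers) <- ACTIVITY_CLASSES
  structure(centers, class = c("seeded_centroids", "matrix"))
}

# Squared Euclidean distances from every row of X to every centroid row.
dist_to_centroids <- function(X, centers) {
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, "+") - 2 * X %*% t(centers)
}

#' Annotate an unlabeled feature set by seeded K-Means
#'
#' Lloyd iterations started at labeled seed centroids: each sample is
#' assigned to the nearest centroid by squared Euclidean distance
#' (ties toward the lowest cluster index), centroids are recomputed as
#' cluster means, and iteration stops at an assignment fixpoint or at
#' `max_iter`. A cluster that loses all members keeps its previous
#' centroid, preserving its labeled anchor. Labels propagate from the
#' seeds through centroid identity.
#'
#' @param X unlabeled feature matrix (rows = windows), same normalized
#'   scale and dimension as the seeds.
#' @param seeds a [seed_centroids()] result.
#' @param max_iter maximum number of assignment/update rounds
#'   (default 100).
#' @return list with `labels` (character, one per row of `X`),
#'   `assignment` (integer cluster indices), `centroids` (final centers),
#'   `iterations` (assignment passes used), `converged` (logical) and
#'   `objective` (within-cluster sum of squares after each iteration,
#'   non-increasing). Emits a warning if `max_iter` is hit before the
#'   fixpoint.
#' @export
kmeans_annotate <- function(X, seeds, max_iter = 100) {
  X <- as.matrix(X)
  stopifnot(inherits(seeds, "seeded_centroids"))
  if (nrow(X) == 0L) stop("X is empty")
  if (ncol(X) != ncol(seeds))
    stop("dimension mismatch: X has ", ncol(X), " features, seeds have ",
         ncol(seeds))
  centers <- unclass(seeds)
  assign_prev <- NULL
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    d2 <- dist_to_centroids(X, centers)
    assignment <- max.col(-d2, ties.method = "first")
    objective <- c(objective,
                   sum(d2[cbind(seq_len(nrow(X)), assignment)]))
    if (identical(assignment, assign_prev)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    iter <- iter + 1L
    assign_prev <- assignment
    for (k in seq_len(nrow(centers))) {
      members <- assignment == k
      if (any(members))
        centers[k, ] <- colMeans(X[members, , drop = FALSE])
    }
  }
  if (!converged)
    warning("seeded K-Means hit max_iter = ", max_iter,
            " before the assignment fixpoint")
  list(labels = rownames(seeds)[assignment],
       assignment = assignment,
       centroids = centers,
       iterations = iter,
       converged = converged,
       objective = objective)
}
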