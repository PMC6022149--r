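#' Fit a multivariate Gaussian model to one activity class
#'
#' Maximum-likelihood fit: `mu` is the sample mean and `sigma` the
#' covariance with divisor m (not m-1), stabilized in two steps. A
#' shrinkage ridge of 1% of the average feature variance is always added:
#' fall-detection scores windows far outside every class's support, where
#' the quadratic form of a near-singular covariance is arbitrary, and the
#' ridge keeps those comparisons governed by the classes' actual spreads.
#' If the matrix is still near-singular (few windows, constant features),
#' `lambda = 1e-6 * trace(sigma)/n` is added repeatedly (up to 10 times)
#' until the smallest eigenvalue exceeds `1e-10` times the largest. The
#' Cholesky factor and log-determinant are cached for density evaluation.
#'
#' @param X feature matrix of the class's samples (rows = windows).
#' @param label optional class label carried on the model.
#' @return object of class `mgd_model` with fields `mu`, `sigma`,
#'   `chol` (upper Cholesky factor), `log_det`, `n_dim`, `n_train`,
#'   `label`.
#' @export
fit_mgd <- function(X, label = NA_character_) {
  X <- as.matrix(X)
  m <- nrow(X)
  if (m < 2L) stop("need at least 2 samples to fit an MGD (got ", m, ")")
  n <- ncol(X)
  mu <- colMeans(X)
  centered <- sweep(X, 2L, mu, "-")
  sigma <- crossprod(centered) / m
  sigma <- (sigma + t(sigma)) / 2
  # shrinkage ridge: 1% of the average feature variance, always applied.
  # Far outside the training support (fall windows sit hundreds of sigma
  # out) the quadratic form of a near-singular covariance is pure
  # extrapolation of within-class correlations and can rank an obviously
  # anomalous window under the tightest class; the ridge bounds the
  # inverse so the widest class dominates far tails.
  lam0 <- 0.01 * sum(diag(sigma)) / n
  if (lam0 > 0) sigma <- sigma + diag(lam0, n)
  for (i in seq_len(10L)) {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 1e-10 * max(ev) && min(ev) > 0) break
    lam <- 1e-6 * sum(diag(sigma)) / n
    if (lam <= 0) lam <- 1e-12
    sigma <- sigma + diag(lam, n)
  }
  R <- chol(sigma)
  structure(list(mu = mu, sigma = sigma, chol = R,
                 log_det = 2 * sum(log(diag(R))),
                 n_dim = n, n_train = m, label = label),
            class = "mgd_model")
}

#' @export
print.mgd_model <- function(x, ...) {
  cat(sprintf("<mgd_model> class %s: %d-dim Gaussian fitted on %d windows\n",
              x$label, x$n_dim, x$n_train))
  invisible(x)
}

#' Log-density under an MGD model
#'
#' Evaluated through the cached Cholesky factor:
#' `-(n/2) log(2 pi) - log|Sigma|/2 - q/2` with the quadratic form
#' `q = (x-mu)' Sigma^-1 (x-mu)` computed by triangular backsolve. All
#' class comparisons are made on this scale; the density itself
#' underflows easily in 13 dimensions.
#'
#' @param model an [fit_mgd()] result.
#' @param x feature vector, or matrix with one vector per row.
#' @return log-density value(s).
#' @export
mgd_log_density <- function(model, x) {
  stopifnot(inherits(model, "mgd_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != model$n_dim)
    stop("dimension mismatch: x has ", ncol(x), " features, model has ",
         model$n_dim)
  if (any(!is.finite(x))) stop("non-finite feature values")
  centered <- sweep(x, 2L, model$mu, "-")
  z <- backsolve(model$chol, t(centered), transpose = TRUE)
  q <- colSums(z^2)
  as.numeric(-0.5 * (model$n_dim * log(2 * pi) + model$log_det + q))
}

#' Density under an MGD model
#'
#' `exp()` of [mgd_log_density()]; may underflow to 0 far from the mean.
#'
#' @inheritParams mgd_log_density
#' @return density value(s).
#' @export
mgd_density <- function(model, x) exp(mgd_log_density(model, x))
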