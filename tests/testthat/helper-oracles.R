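# Independent oracle implementations used to cross-check the package.
# Each is a deliberately naive, straight-line transcription of the
# textbook definition, sharing no code with the implementation under
# test.

# Textbook LOF on one point set (no labels), full sorts, no vectorization.
oracle_lof <- function(X, k) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  kdist <- numeric(n)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    dists <- sapply(setdiff(seq_len(n), i), function(j) d(i, j))
    others <- setdiff(seq_len(n), i)
    ord <- order(dists)
    kd <- dists[ord][k]
    kdist[i] <- kd
    neigh[[i]] <- others[dists <= kd]
  }
  lrd <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in neigh[[i]]) s <- s + max(kdist[j], d(i, j))
    lrd[i] <- if (s == 0) Inf else length(neigh[[i]]) / s
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- lrd[neigh[[i]]] / lrd[i]
    r[is.nan(r)] <- 1
    out[i] <- mean(r)
  }
  out[is.nan(out)] <- 1
  out
}

# Reference multivariate normal density through eigen-decomposition
# whitening and a product of univariate normal densities.
oracle_mvn_density <- function(x, mu, sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  z <- t(e$vectors) %*% (x - mu)
  prod(stats::dnorm(as.numeric(z), mean = 0, sd = sqrt(e$values)))
}

# Two-sided Fisher exact p by full enumeration of tables with the
# observed margins.
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- sapply(a_range, function(a)
    choose(c1, a) * choose(N - c1, r1 - a) / choose(N, r1))
  p_obs <- probs[a_range == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Straight-loop 13-feature extraction from magnitude tracks.
oracle_features <- function(a, w, gyro, rate_hz) {
  six <- function(s) {
    L <- length(s)
    m <- sum(s) / L
    sd_ <- sqrt(sum((s - m)^2) / L)
    en <- sum(s^2) / L
    crossings <- 0
    for (i in 1:(L - 1)) {
      if ((s[i] - m) * (s[i + 1] - m) < 0) crossings <- crossings + 1
    }
    c(m, sd_, en, crossings / (L - 1), max(s), min(s))
  }
  ta <- sqrt(sum(gyro[, 1] / rate_hz)^2 + sum(gyro[, 3] / rate_hz)^2)
  c(six(a), six(w), ta)
}

# deterministic feature matrix with three Gaussian blobs, for
# clustering/LLOF fixtures
make_blobs <- function(n_per, centers, sd, dim = ncol(centers), seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    matrix(stats::rnorm(n_per * dim, mean = rep(centers[k, ], each = n_per),
                        sd = sd), n_per, dim)))
  list(X = X, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# small labelled seed set with the three activity classes at given centers
make_seed_set <- function(centers, n_per = 20, sd = 0.05, seed = 99) {
  b <- make_blobs(n_per, centers, sd, seed = seed)
  list(X = b$X, labels = c("LIA", "MIA", "VIA")[b$truth])
}

rand_windows_stream <- function(n, seed = 1, rate_hz = 50, labels = NULL) {
  set.seed(seed)
  har_stream(matrix(stats::rnorm(n * 6), n, 6), rate_hz = rate_hz,
             labels = labels)
}
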