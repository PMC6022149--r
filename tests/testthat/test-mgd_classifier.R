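make_model <- function(mu, sigma, label = "VIA") {
  sigma <- as.matrix(sigma)
  R <- chol(sigma)
  structure(list(mu = mu, sigma = sigma, chol = R,
                 log_det = 2 * sum(log(diag(R))),
                 n_dim = length(mu), n_train = NA_integer_, label = label),
            class = "mgd_model")
}

identity_normalizer <- function(d = 13) {
  structure(list(min = rep(0, d), range = rep(1, d), method = "minmax"),
            class = "har_normalizer")
}

test_that("MGD fit recovers mean and uses the m-divisor covariance", {
  X <- rbind(rep(0, 13), rep(2, 13))
  m <- fit_mgd(X)
  expect_equal(unname(m$mu), rep(1, 13))
  expect_error(fit_mgd(X[1, , drop = FALSE]), "at least 2")

  # against the closed-form MLE (before the shrinkage ridge)
  set.seed(30)
  X2 <- matrix(rnorm(50 * 3), 50, 3)
  m2 <- fit_mgd(X2)
  centered <- sweep(X2, 2, colMeans(X2))
  mle <- crossprod(centered) / 50
  ridge <- 0.01 * mean(diag(mle))
  expect_equal(m2$sigma, mle + diag(ridge, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # identical samples: regularization yields a tiny positive-definite matrix
  m3 <- fit_mgd(matrix(1, 5, 4))
  ev <- eigen(m3$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_lt(max(ev), 1e-6)
})

test_that("density evaluation matches the closed form and a reference pdf", {
  m1 <- make_model(0, matrix(1, 1, 1))
  expect_equal(mgd_density(m1, 0), 1 / sqrt(2 * pi))

  set.seed(31)
  A <- matrix(rnorm(169), 13, 13)
  sigma <- crossprod(A) / 13 + diag(0.5, 13)
  mu <- rnorm(13)
  m <- make_model(mu, sigma)
  # at the mean the density is the normalizing constant
  expect_equal(mgd_density(m, mu),
               (2 * pi)^(-13 / 2) * det(sigma)^(-1 / 2), tolerance = 1e-12)
  for (i in 1:20) {
    x <- mu + rnorm(13)
    expect_equal(mgd_density(m, x), oracle_mvn_density(x, mu, sigma),
                 tolerance = 1e-10)
  }
  expect_error(mgd_density(m, rep(NaN, 13)), "finite")
})

test_that("a known 13-D Gaussian is recovered from 5000 draws", {
  set.seed(2024)
  d <- 13
  A <- matrix(rnorm(d * d, sd = 0.3), d, d)
  sigma <- crossprod(A)
  D <- diag(1 / sqrt(diag(sigma)))
  sigma <- D %*% sigma %*% D  # unit variances
  mu <- runif(d, -1, 1)
  X <- MASS::mvrnorm(5000, mu, sigma)
  fit <- fit_mgd(X)
  expect_lt(max(abs(fit$mu - mu)), 0.05)
  expect_lt(max(abs(fit$sigma - sigma)), 0.1)
})

test_that("the decision rule follows the class-index and fall-threshold branches", {
  d <- 13
  mk <- function(center) make_model(rep(center, d), diag(0.01, d))
  models <- list(LIA = mk(0.1), MIA = mk(0.5), VIA = mk(0.9))
  clf <- personalized_classifier(models, identity_normalizer(d),
                                 eps2 = 1e-6, eps3 = 60)

  near_lia <- rep(0.1, d)  # tilt 0.1 deg, well under eps3
  expect_equal(classify_window(clf, near_lia), "LIA")
  near_mia <- rep(0.5, d)
  expect_equal(classify_window(clf, near_mia), "MIA")

  # vigorous-looking, high density, small tilt -> VIA
  near_via <- rep(0.9, d); near_via[13] <- 0.9
  expect_equal(classify_window(clf, near_via), "VIA")

  # anomalous under p3 and large tilt -> Fall
  fall_like <- rep(3, d); fall_like[13] <- 90
  expect_equal(classify_window(clf, fall_like), "Fall")

  # incoherent combinations resolve to VIA (both conditions required);
  # the VIA model here tolerates any tilt so its density stays high
  via_wide_ta <- make_model(rep(0.9, d), diag(c(rep(0.01, 12), 1e4)))
  models_wide <- list(LIA = mk(0.1), MIA = mk(0.5), VIA = via_wide_ta)
  clf_wide <- personalized_classifier(models_wide, identity_normalizer(d),
                                      eps2 = 1e-30, eps3 = 60)
  high_density_big_tilt <- rep(0.9, d); high_density_big_tilt[13] <- 90
  expect_equal(classify_window(clf_wide, high_density_big_tilt), "VIA")
  anomalous_small_tilt <- rep(3, d); anomalous_small_tilt[13] <- 5
  expect_equal(classify_window(clf, anomalous_small_tilt), "VIA")
})

test_that("argmax agrees with the true Bayes rule on data from the fitted models", {
  set.seed(33)
  d <- 13
  mus <- list(runif(d, 0, 0.3), runif(d, 0.3, 0.6), runif(d, 0.6, 1))
  sigmas <- lapply(1:3, function(i) {
    A <- matrix(rnorm(d * d, sd = 0.05), d, d); crossprod(A) + diag(0.01, d)
  })
  models <- list(LIA = make_model(mus[[1]], sigmas[[1]], "LIA"),
                 MIA = make_model(mus[[2]], sigmas[[2]], "MIA"),
                 VIA = make_model(mus[[3]], sigmas[[3]], "VIA"))
  clf <- personalized_classifier(models, identity_normalizer(d),
                                 eps2 = 1e-300, eps3 = 1e9)
  agree <- 0; total <- 0
  for (k in 1:3) {
    X <- MASS::mvrnorm(500, mus[[k]], sigmas[[k]])
    pred <- classify_window(clf, X)
    truth <- apply(X, 1, function(x) {
      dens <- vapply(1:3, function(j)
        oracle_mvn_density(x, mus[[j]], sigmas[[j]]), numeric(1))
      c("LIA", "MIA", "VIA")[which.max(dens)]
    })
    agree <- agree + sum(pred == truth); total <- total + length(truth)
  }
  expect_gte(agree / total, 0.99)
})

test_that("threshold calibration tracks the density percentile of the vigorous class", {
  set.seed(34)
  X <- matrix(rnorm(100 * 13, sd = 0.1), 100, 13)
  m <- fit_mgd(X, "VIA")
  dens <- mgd_density(m, X)
  thr0 <- calibrate_thresholds(m, X, percentile = 0)
  expect_equal(thr0$eps2, min(dens), tolerance = 1e-9)
  expect_equal(thr0$eps3, 60)
  thr1 <- calibrate_thresholds(m, X, percentile = 1)
  expect_lte(thr1$eps2, max(dens))
  expect_gte(thr1$eps2, min(dens))
  # all densities at least d0 implies eps2 <= d0 for any percentile
  expect_lte(thr1$eps2, sort(dens)[2])
  expect_warning(thr <- calibrate_thresholds(m, X[1:10, ]), "fewer than 20")
  expect_equal(thr$eps2, 1e-12)
})

test_that("the full adaptive pipeline orders class intensities and is deterministic", {
  prof <- subject_profile(seed = 77)
  stream <- simulate_subject(prof, session_script(
    c("LIA", "MIA", "VIA"), c(30, 30, 30)))
  seed_set <- local({
    prof2 <- subject_profile(seed = 78)
    s2 <- simulate_subject(prof2, session_script(
      c("LIA", "MIA", "VIA"), c(30, 30, 30)))
    s2 <- separate_gravity(s2)
    X <- window_features(segment_windows(s2))
    list(X = X, labels = attr(X, "labels"))
  })
  clf <- train_personalized(stream, seed_set$X, seed_set$labels)
  mus <- sapply(clf$models, function(m) unname(m$mu["a_std"]))
  expect_true(mus[["LIA"]] < mus[["MIA"]] && mus[["MIA"]] < mus[["VIA"]])

  sizes <- unlist(clf$report$class_sizes)
  expect_equal(sum(sizes), clf$report$n_windows - clf$report$n_removed)

  clf2 <- train_personalized(stream, seed_set$X, seed_set$labels)
  expect_identical(clf[setdiff(names(clf), "report")],
                   clf2[setdiff(names(clf2), "report")])

  # an infinite LLOF threshold reproduces the unfiltered pipeline
  cfg_inf <- har_config(llof_eps1 = Inf)
  clf_inf <- train_personalized(stream, seed_set$X, seed_set$labels, cfg_inf)
  expect_equal(clf_inf$report$n_removed, 0L)
})

test_that("classifiers survive a JSON round trip", {
  prof <- subject_profile(seed = 79)
  stream <- simulate_subject(prof, session_script(
    c("LIA", "MIA", "VIA"), c(20, 20, 20)))
  seed_stream <- simulate_subject(subject_profile(seed = 80),
                                  session_script(c("LIA", "MIA", "VIA"),
                                                 c(20, 20, 20)))
  s2 <- separate_gravity(seed_stream)
  Xs <- window_features(segment_windows(s2))
  clf <- train_personalized(stream, Xs, attr(Xs, "labels"))
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  clf2 <- read_classifier(path)
  test_stream <- simulate_subject(subject_profile(seed = 81),
                                  session_script(c("LIA", "MIA", "VIA", "Fall"),
                                                 c(5, 5, 5, 4.5)))
  p1 <- classify_stream(clf, test_stream)
  p2 <- classify_stream(clf2, test_stream)
  expect_equal(p1$predicted, p2$predicted)
})
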