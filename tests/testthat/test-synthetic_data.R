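test_that("simulation is reproducible from the profile seed", {
  prof <- subject_profile(seed = 123)
  s1 <- simulate_subject(prof)
  s2 <- simulate_subject(prof)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$labels, s2$labels)
})

test_that("label track durations match the script", {
  script <- session_script(c("LIA", "VIA", "Fall", "MIA"),
                           c(10, 5.5, 4.5, 8))
  st <- simulate_subject(subject_profile(seed = 5), script)
  expect_equal(nrow(st$samples), sum(script$duration_s) * 50)
  expect_length(st$labels, nrow(st$samples))
  # the fall event is 2 s of Fall samples inside the Fall segment
  expect_equal(sum(st$labels == "Fall"), 100L)
  # non-fall segment labels are exactly as scripted
  expect_equal(st$labels[1:500], rep("LIA", 500))
  expect_equal(st$labels[501:775], rep("VIA", 275))
})

test_that("windowed intensity orders the classes within every subject", {
  cohort <- make_cohort(n_subjects = 4, master_seed = 11)
  for (subj in cohort) {
    st <- separate_gravity(subj$stream)
    X <- window_features(segment_windows(st))
    labs <- attr(X, "labels")
    m <- tapply(X[, "a_std"], labs, mean)
    expect_true(m[["LIA"]] < m[["MIA"]] && m[["MIA"]] < m[["VIA"]])
  }
})

test_that("every 300-ms fall transient fits entirely inside at least one window", {
  cohort <- make_cohort(n_subjects = 3, master_seed = 21)
  for (subj in cohort) {
    labs <- subj$stream$labels
    runs <- rle(labs)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    fall_starts <- starts[runs$values == "Fall"]
    expect_gt(length(fall_starts), 0L)
    for (s0 in fall_starts) {
      # impact pulse: first 15 samples of the event (0-based s0-1),
      # and recovery pulse at +50; both must fit in a 50-sample window
      for (p0 in c(s0 - 1L, s0 - 1L + 50L)) {
        containing <- sum(vapply(seq(0, nrow(subj$stream$samples) - 50, by = 25),
                                 function(w) w <= p0 && (p0 + 15) <= w + 50,
                                 logical(1)))
        expect_gte(containing, 1L)
      }
    }
  }
})

test_that("fall windows carry a near-90-degree tilt angle", {
  st <- simulate_subject(subject_profile(seed = 31),
                         session_script(c("VIA", "Fall", "VIA"),
                                        c(10, 4.5, 10)))
  st <- separate_gravity(st)
  X <- window_features(segment_windows(st))
  fall_w <- attr(X, "labels") == "Fall"
  expect_gt(sum(fall_w), 0L)
  expect_gt(max(X[fall_w, "tilt_angle"]), 70)
})

test_that("cohorts are seed-stable with distinct subject profiles", {
  c1 <- make_cohort(n_subjects = 10, master_seed = 7)
  c2 <- make_cohort(n_subjects = 10, master_seed = 7)
  expect_length(c1, 10L)
  expect_identical(c1[[3]]$stream$samples, c2[[3]]$stream$samples)
  amps <- t(sapply(c1, function(s) s$profile$amp_mult))
  expect_gt(max(amps) - min(amps), 0.1)  # real spread
  expect_error(make_cohort(n_subjects = 1), "at least 2")
})

test_that("between-subject shift exceeds within-subject scatter for some class", {
  cohort <- make_cohort(n_subjects = 5, master_seed = 13)
  feats <- lapply(cohort, function(subj) {
    st <- separate_gravity(subj$stream)
    X <- window_features(segment_windows(st))
    list(X = X, labs = attr(X, "labels"))
  })
  separated <- vapply(c("LIA", "MIA", "VIA"), function(cl) {
    means <- t(sapply(feats, function(f)
      colMeans(f$X[f$labs == cl, , drop = FALSE])))
    between <- mean(dist(means))
    within <- mean(sapply(feats, function(f) {
      Xc <- f$X[f$labs == cl, , drop = FALSE]
      mean(sqrt(rowSums(sweep(Xc, 2, colMeans(Xc))^2)))
    }))
    between > within
  }, logical(1))
  expect_true(any(separated))
})
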