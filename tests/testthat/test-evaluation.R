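test_that("one-vs-rest confusion counts match hand counts", {
  truth <- c(rep("LIA", 5), rep("Fall", 5))
  pred <- c(rep("LIA", 5), rep("Fall", 4), "LIA")
  cc <- confusion_counts(truth, pred, positive = "Fall")
  expect_equal(cc$Tp, 4L)
  expect_equal(cc$Fn, 1L)
  expect_equal(cc$Fp, 0L)
  expect_equal(cc$Tp + cc$Fp + cc$Fn + cc$Tn, 10L)

  perfect <- confusion_counts(truth, truth, "Fall")
  expect_equal(perfect$Fp + perfect$Fn, 0L)
  all_wrong <- confusion_counts(truth, rev(truth), "Fall")
  expect_equal(all_wrong$Tp, 0L)
  expect_error(confusion_counts(truth, pred[1:5], "Fall"), "lengths differ")
})

test_that("F-measure is the harmonic mean with the degenerate-zero rule", {
  f1 <- f_measure(confusion_counts(rep("A", 10), rep("A", 10), "A"))
  expect_equal(unname(f1), c(1, 1, 1))

  cc <- structure(list(Tp = 8, Fp = 2, Fn = 2, Tn = 10, positive = "A"),
                  class = "confusion_counts")
  expect_equal(unname(f_measure(cc)), c(0.8, 0.8, 0.8))

  cc0 <- structure(list(Tp = 0, Fp = 3, Fn = 4, Tn = 10, positive = "A"),
                   class = "confusion_counts")
  expect_equal(unname(f_measure(cc0)[["f_measure"]]), 0)

  ccd <- structure(list(Tp = 0, Fp = 0, Fn = 4, Tn = 10, positive = "A"),
                   class = "confusion_counts")
  expect_warning(fd <- f_measure(ccd), "degenerate")
  expect_equal(unname(fd[["f_measure"]]), 0)

  # min(P,R) <= F <= max(P,R) on random counts
  set.seed(41)
  for (i in 1:25) {
    v <- sample(1:30, 4, replace = TRUE)
    cc <- structure(list(Tp = v[1], Fp = v[2], Fn = v[3], Tn = v[4],
                         positive = "A"), class = "confusion_counts")
    pr <- f_measure(cc)
    expect_gte(pr[["f_measure"]], min(pr[["precision"]], pr[["recall"]]) - 1e-12)
    expect_lte(pr[["f_measure"]], max(pr[["precision"]], pr[["recall"]]) + 1e-12)
  }
})

test_that("Fisher's exact test reproduces the enumeration oracle", {
  tab <- matrix(c(1, 4, 5, 0), 2, 2)
  p <- fisher_exact_2x2(tab)
  expect_lt(p, 0.05)
  expect_equal(p, 12 / 252, tolerance = 1e-9)
  expect_equal(p, oracle_fisher_2x2(tab), tolerance = 1e-9)

  expect_equal(fisher_exact_2x2(matrix(5, 2, 2)), 1)

  # transposition and simultaneous row+column swap leave p unchanged
  set.seed(42)
  for (i in 1:20) {
    tab <- matrix(sample(1:8, 4, replace = TRUE), 2, 2)
    p0 <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(t(tab)), p0, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p0, tolerance = 1e-12)
    expect_equal(p0, oracle_fisher_2x2(tab), tolerance = 1e-9)
  }

  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margins")
})

test_that("above-mean improvement splits cross-tabulate against a covariate", {
  deltas <- c(0.01, 0.03, 0.04, 0.035, 0.002, 0.05, 0.045, 0.038, 0.001, 0.003)
  normal_bmi <- c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, TRUE,
                  TRUE, TRUE)
  res <- improvement_association(deltas, normal_bmi)
  expect_equal(dim(res$table), c(2L, 2L))
  expect_equal(sum(res$table), 10)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("LOO report has the right shape and near-zero deltas for identical subjects", {
  script <- session_script(c("LIA", "MIA", "VIA", "LIA", "MIA", "VIA", "Fall"),
                           c(20, 20, 20, 3, 3, 3, 6))
  cohort <- make_cohort(n_subjects = 4, script = script, master_seed = 3,
                        subject_shift = 0)
  rep <- loo_generic_vs_personalized(cohort, har_config())
  expect_s3_class(rep, "har_eval_report")
  expect_equal(nrow(rep$per_subject), 4L * 4L)
  expect_setequal(unique(rep$per_subject$class), c("LIA", "MIA", "VIA", "Fall"))
  expect_true(all(rep$summary$f_personalized >= 0 &
                  rep$summary$f_personalized <= 1, na.rm = TRUE))
  expect_lt(max(abs(rep$summary$delta), na.rm = TRUE), 0.1)
  expect_error(loo_generic_vs_personalized(cohort[1:2]), "at least 3")
})
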