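#' One-vs-rest confusion counts
#'
#' @param truth,predicted equal-length label vectors.
#' @param positive the class treated as positive.
#' @return object of class `confusion_counts` with fields `Tp`, `Fp`,
#'   `Fn`, `Tn` summing to the number of evaluated windows.
#' @export
confusion_counts <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ (",
         length(truth), " vs ", length(predicted), ")")
  pos_t <- truth == positive
  pos_p <- predicted == positive
  structure(list(Tp = sum(pos_t & pos_p),
                 Fp = sum(!pos_t & pos_p),
                 Fn = sum(pos_t & !pos_p),
                 Tn = sum(!pos_t & !pos_p),
                 positive = positive),
            class = "confusion_counts")
}

#' Precision, recall and F-measure
#'
#' `P = Tp/(Tp+Fp)`, `R = Tp/(Tp+Fn)`, `F = 2PR/(P+R)`. A degenerate
#' denominator (no predicted positives, no true positives, or `P+R = 0`)
#' yields 0 with a warning rather than `NaN`, so per-subject reports stay
#' aggregable.
#'
#' @param counts a [confusion_counts()] object.
#' @return named numeric vector `c(precision, recall, f_measure)`.
#' @export
f_measure <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  p_den <- counts$Tp + counts$Fp
  r_den <- counts$Tp + counts$Fn
  if (p_den == 0 || r_den == 0) {
    warning("degenerate confusion counts for class '", counts$positive,
            "'; reporting 0")
    p <- if (p_den == 0) 0 else counts$Tp / p_den
    r <- if (r_den == 0) 0 else counts$Tp / r_den
  } else {
    p <- counts$Tp / p_den
    r <- counts$Tp / r_den
  }
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f_measure = f)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value with the standard "sum all tables whose
#' hypergeometric probability does not exceed the observed table's"
#' convention, computed by [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts; all row and
#'   column margins must be positive.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all table margins must be positive")
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Split a per-subject improvement vector on a binary covariate
#'
#' Utility behind the cohort significance analysis: subjects improving
#' more than the cohort mean are "significant subjects", the rest are
#' not, and the 2x2 cross-table against any binary covariate (for
#' example, BMI in or outside the normal range) can be passed to
#' [fisher_exact_2x2()].
#'
#' @param deltas per-subject improvement values (personalized minus
#'   generic mean F-measure).
#' @param covariate logical or two-level vector, one entry per subject.
#' @return list with the 2x2 `table` (rows: above/below-mean improvement;
#'   columns: covariate levels) and the Fisher `p_value`.
#' @export
improvement_association <- function(deltas, covariate) {
  if (length(deltas) != length(covariate))
    stop("deltas and covariate lengths differ")
  ss <- factor(deltas > mean(deltas), levels = c(TRUE, FALSE),
               labels = c("SS", "IS"))
  tab <- table(ss, factor(covariate))
  list(table = tab, p_value = fisher_exact_2x2(tab))
}

# per-subject windowed features for one contiguous sample range
split_features <- function(stream, from, to, config) {
  sub <- har_stream(stream$samples[from:to, , drop = FALSE],
                    rate_hz = stream$rate_hz,
                    labels = if (!is.null(stream$labels))
                      stream$labels[from:to] else NULL)
  sub <- separate_gravity(sub, cutoff_hz = config$gravity_cutoff_hz,
                          order = config$butter_order)
  windows <- segment_windows(sub, window_s = config$window_s,
                             overlap = config$overlap)
  list(stream = sub, features = window_features(windows))
}

#' Leave-one-out generic-versus-personalized comparison
#'
#' For every subject the stream is split 4:1 in time; the training split
#' must be fall-free (falls are test-only by protocol). The
#' *personalized* classifier runs the full adaptive pipeline on the
#' subject's own unlabeled training split, using the other subjects'
#' pooled labeled training windows only to seed the annotation. The
#' *generic* classifier is fitted directly on those pooled labeled
#' windows, never seeing the held-out subject. Both classify the same
#' held-out test windows (falls included) and per-class F-measures are
#' compared.
#'
#' @param cohort a [make_cohort()] result (each element: `profile`,
#'   `stream` with label track).
#' @param config a [har_config()].
#' @param split_frac fraction of samples used for training (default 0.8,
#'   the 4:1 protocol ratio).
#' @return object of class `har_eval_report`: `per_subject` (data frame
#'   of subject x class F-measures for both classifiers and their delta)
#'   and `summary` (per-class means; `delta` is personalized minus
#'   generic).
#' @export
loo_generic_vs_personalized <- function(cohort, config = har_config(),
                                        split_frac = 0.8) {
  if (length(cohort) < 3L) stop("need at least 3 subjects for the protocol")
  n_sub <- length(cohort)

  parts <- lapply(cohort, function(subj) {
    stream <- subj$stream
    if (is.null(stream$labels))
      stop("cohort streams must carry ground-truth labels")
    n <- nrow(stream$samples)
    cut <- floor(n * split_frac)
    train <- split_features(stream, 1L, cut, config)
    if (any(train$stream$labels == "Fall"))
      stop("subject ", subj$profile$id,
           ": training split contains fall samples; falls are test-only")
    test <- split_features(stream, cut + 1L, n, config)
    list(train = train, test = test)
  })

  rows <- list()
  for (s in seq_len(n_sub)) {
    others <- setdiff(seq_len(n_sub), s)
    pool_X <- do.call(rbind, lapply(parts[others],
                                    function(p) p$train$features))
    pool_labels <- unlist(lapply(parts[others],
                                 function(p) attr(p$train$features, "labels")))

    pers <- train_personalized(parts[[s]]$train$stream,
                               pool_X, pool_labels, config)
    gen <- train_generic(pool_X, pool_labels, config)

    Xte <- parts[[s]]$test$features
    truth <- attr(Xte, "labels")
    pred_p <- classify_window(pers, Xte)
    pred_g <- classify_window(gen, Xte)

    for (cl in ALL_CLASSES) {
      if (!any(truth == cl)) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, class = cl, f_personalized = NA_real_,
          f_generic = NA_real_, delta = NA_real_)
        next
      }
      fp <- suppressWarnings(
        f_measure(confusion_counts(truth, pred_p, cl))[["f_measure"]])
      fg <- suppressWarnings(
        f_measure(confusion_counts(truth, pred_g, cl))[["f_measure"]])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, class = cl, f_personalized = fp,
        f_generic = fg, delta = fp - fg)
    }
  }
  per_subject <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(ALL_CLASSES, function(cl) {
    d <- per_subject[per_subject$class == cl, ]
    data.frame(class = cl,
               f_personalized = mean(d$f_personalized, na.rm = TRUE),
               f_generic = mean(d$f_generic, na.rm = TRUE),
               delta = mean(d$delta, na.rm = TRUE))
  }))
  structure(list(per_subject = per_subject, summary = summary,
                 n_subjects = n_sub, split_frac = split_frac),
            class = "har_eval_report")
}

#' @export
print.har_eval_report <- function(x, ...) {
  cat(sprintf("<har_eval_report> %d subjects, %.0f:%.0f train:test split\n",
              x$n_subjects, x$split_frac * 10, (1 - x$split_frac) * 10))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
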