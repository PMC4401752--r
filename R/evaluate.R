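#' Tabulate confusion counts from truth and calls
#'
#' @param truth Logical vector (or `"positive"`/`"negative"` labels): the true
#'   class of each window.
#' @param call Logical vector: the classifier's calls.
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, call) {
  if (is.character(truth)) truth <- truth == "positive"
  stopifnot(length(truth) == length(call))
  tibble(
    tp = sum(truth & call), fp = sum(!truth & call),
    tn = sum(!truth & !call), fn = sum(truth & !call)
  )
}

#' F-measure (harmonic mean of precision and recall)
#'
#' @param precision,recall Proportions in `[0, 1]`.
#' @return `2 * precision * recall / (precision + recall)`, or 0 when both are 0.
#' @export
#' @examples
#' f_measure(0.7680, 0.8205) # ~0.7933
f_measure <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Classification metrics from confusion counts
#'
#' Computes precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy
#' `(TP+TN)/total`, F-measure (harmonic mean of precision and recall),
#' sensitivity (= recall) and specificity `TN/(TN+FP)`. A degenerate
#' denominator (e.g. no predicted positives) yields 0 for the affected metric
#' and sets the `degenerate` flag instead of erroring, so resampling loops
#' never abort.
#'
#' @param counts A data frame or named vector/list with `tp`, `fp`, `tn`, `fn`
#'   (e.g. from [confusion_counts()]).
#' @return A one-row tibble with `precision`, `recall`, `accuracy`,
#'   `f_measure`, `sn`, `sp` and `degenerate`.
#' @export
#' @examples
#' compute_metrics(list(tp = 96, fp = 29, tn = 1143, fn = 21))
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp
  fp <- counts$fp
  tn <- counts$tn
  fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) {
    abort("confusion counts must be non-negative", class = "phosgram_config_error")
  }
  total <- tp + fp + tn + fn
  if (total == 0) {
    abort("cannot compute metrics from an empty evaluation",
      class = "phosgram_empty_evaluation_error"
    )
  }
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  sp <- safe_div(tn, tn + fp)
  degenerate <- (tp + fp == 0) || (tp + fn == 0) || (tn + fp == 0)
  tibble(
    precision = precision, recall = recall,
    accuracy = (tp + tn) / total,
    f_measure = f_measure(precision, recall),
    sn = recall, sp = sp, degenerate = degenerate
  )
}

#' ROC points over a threshold grid
#'
#' For each threshold, windows scoring at least the threshold are called
#' positive and sensitivity / specificity are tabulated. Sensitivity is
#' non-increasing as the threshold rises.
#'
#' @param scores Data frame with a probability column (`probability` or
#'   `score`) and a `label` column (logical or `"positive"`/`"negative"`).
#' @param grid Thresholds in `[0, 1]`; default the conventional sweep 0.001 to
#'   0.010 in steps of 0.0005.
#' @return A tibble of class `phosgram_roc` with `threshold`, `sn`, `sp`,
#'   `fpr` (= 1 - sp).
#' @export
roc_points <- function(scores, grid = seq(0.001, 0.010, by = 0.0005)) {
  scores <- as_tibble(scores)
  prob_col <- intersect(c("probability", "score"), names(scores))[1]
  if (is.na(prob_col) || !"label" %in% names(scores)) {
    abort("scores need a probability/score column and a label column",
      class = "phosgram_type_error"
    )
  }
  truth <- scores$label
  if (is.character(truth)) truth <- truth == "positive"
  if (all(truth) || !any(truth)) {
    abort("ROC needs both positive and negative labels",
      class = "phosgram_degenerate_roc_error"
    )
  }
  if (any(grid < 0 | grid > 1)) {
    abort("grid thresholds must be in [0, 1]", class = "phosgram_config_error")
  }
  p <- scores[[prob_col]]
  out <- purrr::map_dfr(grid, function(th) {
    m <- compute_metrics(confusion_counts(truth, p >= th))
    tibble(threshold = th, sn = m$sn, sp = m$sp, fpr = 1 - m$sp)
  })
  class(out) <- c("phosgram_roc", class(out))
  out
}

## ---- learners -------------------------------------------------------------

#' Learner constructors for the evaluation protocol
#'
#' A learner is a function `(train_positives, train_negatives) -> classifier`,
#' where the classifier maps a character vector of windows to logical calls.
#' [cross_validate()] and [bootstrap_evaluate()] are agnostic to which learner
#' they drive. The Alergia learner trains on positives only (negatives are
#' ignored, as the generative model requires); the RPNI and GA learners
#' consume both sets.
#'
#' @param alpha,smoothing,min_count Alergia parameters (see [infer_dsfa()]).
#' @param threshold Decision threshold for the Alergia classifier.
#' @param config A [ga_config()] for the GA learner.
#' @param alphabet Symbol set.
#' @return A function of class `phosgram_learner`.
#' @name learners
NULL

#' @rdname learners
#' @export
alergia_learner <- function(alpha = 0.7, smoothing = 0.01, threshold = 0.008,
                            min_count = 0, alphabet = aa_alphabet()) {
  structure(
    function(train_positives, train_negatives = character(0)) {
      model <- infer_dsfa(train_positives,
        alpha = alpha, smoothing = smoothing,
        min_count = min_count, alphabet = alphabet
      )
      function(w) sequence_probability(model, w) >= threshold
    },
    class = c("phosgram_learner", "function")
  )
}

#' @rdname learners
#' @export
rpni_learner <- function(alphabet = aa_alphabet()) {
  structure(
    function(train_positives, train_negatives) {
      model <- rpni(train_positives, train_negatives, alphabet = alphabet)
      function(w) dfa_accepts(model, w)
    },
    class = c("phosgram_learner", "function")
  )
}

#' @rdname learners
#' @export
ga_learner <- function(config = ga_config(), alphabet = aa_alphabet()) {
  structure(
    function(train_positives, train_negatives) {
      model <- ga_infer(train_positives, train_negatives,
        config = config,
        alphabet = alphabet
      )
      function(w) dfa_accepts(model, w)
    },
    class = c("phosgram_learner", "function")
  )
}

## ---- cross-validation and bootstrap ---------------------------------------

#' k-fold cross-validation with a fixed test class ratio
#'
#' Positives are shuffled (seeded) into `k` near-equal folds. For each fold
#' the learner trains on the other `k - 1` parts; the held-out positives plus
#' `neg_ratio` times as many negatives (sampled without replacement from the
#' pool, fresh per fold with a fold-derived seed) form the test set. Training
#' negatives passed to the learner are the negatives not used in that fold's
#' test set. Mean metrics over folds are returned.
#'
#' @param positives,negatives Windows data frames or character vectors.
#' @param learner A learner function (see [learners]).
#' @param k Number of folds (default 10).
#' @param neg_ratio Test negatives per positive (default 10).
#' @param seed Integer seed.
#' @return A one-row tibble of mean metrics; per-fold metrics in
#'   `attr(, "folds")`.
#' @export
cross_validate <- function(positives, negatives, learner, k = 10,
                           neg_ratio = 10, seed = NULL) {
  pos <- window_strings(positives, "positives")
  neg <- window_strings(negatives, "negatives")
  if (k < 2) abort("k must be >= 2", class = "phosgram_config_error")
  if (length(pos) < k) {
    abort(sprintf("%d positives cannot fill %d folds", length(pos), k),
      class = "phosgram_fold_error"
    )
  }
  fold_of <- with_seed_(seed, sample(rep_len(seq_len(k), length(pos))))
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    test_pos <- pos[fold_of == f]
    train_pos <- pos[fold_of != f]
    n_neg <- neg_ratio * length(test_pos)
    if (length(neg) < n_neg) {
      abort(
        sprintf("negative pool (%d) too small for a 1:%d test ratio", length(neg), neg_ratio),
        class = "phosgram_ratio_error"
      )
    }
    idx <- with_seed_(
      if (is.null(base_seed)) NULL else base_seed + f,
      sample.int(length(neg), n_neg)
    )
    test_neg <- neg[idx]
    train_neg <- neg[-idx]
    classifier <- learner(train_pos, train_neg)
    calls <- classifier(c(test_pos, test_neg))
    truth <- rep(c(TRUE, FALSE), c(length(test_pos), length(test_neg)))
    m <- compute_metrics(confusion_counts(truth, calls))
    dplyr::bind_cols(tibble(fold = f), m)
  })
  out <- dplyr::summarise(folds, dplyr::across(
    c("precision", "recall", "accuracy", "f_measure", "sn", "sp"), mean
  ))
  out$degenerate <- any(folds$degenerate)
  attr(out, "folds") <- folds
  out
}

#' Asymmetric bootstrap evaluation
#'
#' Draws `B` bootstrap resamples of the positive set (with replacement, each
#' of the original size) and runs a seeded k-fold cross-validation on each;
#' the negative pool is left as is and sampled inside the folds to the 1:`
#' neg_ratio` test ratio. One row of mean metrics per resample.
#'
#' @inheritParams cross_validate
#' @param B Number of bootstrap resamples (>= 1).
#' @return A tibble of class `phosgram_boot` with a `resample` column plus the
#'   mean metrics of each resample's cross-validation.
#' @export
bootstrap_evaluate <- function(positives, negatives, learner, B = 10, k = 10,
                               neg_ratio = 10, seed = NULL) {
  if (B < 1) abort("B must be >= 1", class = "phosgram_config_error")
  pos <- window_strings(positives, "positives")
  neg <- window_strings(negatives, "negatives")
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  out <- purrr::map_dfr(seq_len(B), function(b) {
    rs_seed <- if (is.null(base_seed)) NULL else base_seed + 1000L * b
    resample <- with_seed_(rs_seed, sample(pos, length(pos), replace = TRUE))
    m <- cross_validate(resample, neg, learner,
      k = k, neg_ratio = neg_ratio,
      seed = rs_seed
    )
    dplyr::bind_cols(tibble(resample = b), m)
  })
  class(out) <- c("phosgram_boot", class(out))
  out
}

#' One-sided paired t-test on accuracy series
#'
#' Classic paired t-test on the differences `a - b` with alternative
#' "mean difference > 0" and `n - 1` degrees of freedom; the null is rejected
#' at the 5% level. Two identical series give `t = 0`, `p = 0.5`.
#'
#' @param acc_a,acc_b Equal-length numeric vectors (length >= 2), e.g.
#'   per-split accuracies of two methods.
#' @return A one-row tibble with `t`, `df`, `p_value`, `reject`.
#' @export
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 1, 1)) # t ~ 3.46, p ~ 0.037
paired_t_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) {
    abort("paired series must have equal length", class = "phosgram_pairing_error")
  }
  if (length(acc_a) < 2) {
    abort("need at least two pairs", class = "phosgram_sample_size_error")
  }
  d <- acc_a - acc_b
  n <- length(d)
  if (stats::sd(d) == 0) {
    # degenerate: constant differences; the t statistic is 0 or +/- infinity
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
    return(tibble(t = t_stat, df = n - 1, p_value = p, reject = p < 0.05))
  }
  ht <- stats::t.test(acc_a, acc_b, paired = TRUE, alternative = "greater")
  tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, reject = ht$p.value < 0.05
  )
}

#' Compare grammar-inference methods on repeated splits
#'
#' Runs each learner on the same `n_repeats` independent train/test splits
#' (60/40 positives by default, test negatives at the 1:`neg_ratio` ratio) and
#' reports per-split accuracies plus one-sided paired t-tests of the first
#' (reference) learner against each other learner.
#'
#' @param positives,negatives Windows data frames or character vectors.
#' @param learners Named list of learner functions; the first is the
#'   reference method.
#' @param n_repeats Number of independent splits (default 10).
#' @param train_fraction,neg_ratio Split parameters (defaults 0.6 and 10).
#' @param seed Integer seed.
#' @return A list with `metrics` (tibble: split, method, accuracy, ...) and
#'   `t_tests` (tibble: comparison, t, df, p_value, reject).
#' @export
compare_gi <- function(positives, negatives, learners, n_repeats = 10,
                       train_fraction = 0.6, neg_ratio = 10, seed = NULL) {
  stopifnot(is.list(learners), length(learners) >= 2, !is.null(names(learners)))
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  metrics <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    split <- assemble_split(positives, negatives,
      train_fraction = train_fraction, neg_ratio = neg_ratio,
      seed = if (is.null(base_seed)) NULL else base_seed + r
    )
    test_w <- c(split$test_positives$window, split$test_negatives$window)
    truth <- rep(c(TRUE, FALSE), c(nrow(split$test_positives), nrow(split$test_negatives)))
    # training negatives for the discriminative baselines: pool minus the test sample
    train_neg <- setdiff(window_strings(negatives, "negatives"), split$test_negatives$window)
    purrr::map_dfr(names(learners), function(nm) {
      classifier <- learners[[nm]](split$train_positives$window, train_neg)
      m <- compute_metrics(confusion_counts(truth, classifier(test_w)))
      dplyr::bind_cols(tibble(split = r, method = nm), m)
    })
  })
  ref <- names(learners)[1]
  others <- setdiff(names(learners), ref)
  acc <- function(nm) metrics$accuracy[metrics$method == nm][order(metrics$split[metrics$method == nm])]
  t_tests <- purrr::map_dfr(others, function(nm) {
    dplyr::bind_cols(
      tibble(comparison = paste(ref, "vs", nm)),
      paired_t_test(acc(ref), acc(nm))
    )
  })
  list(metrics = metrics, t_tests = t_tests)
}
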