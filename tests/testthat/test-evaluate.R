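test_that("metric identities hold against an independent recount", {
  withr::with_seed(43, {
    for (rep in 1:20) {
      n <- sample(20:200, 1)
      truth <- stats::runif(n) < 0.3
      call <- stats::runif(n) < 0.4
      cc <- confusion_counts(truth, call)
      m <- compute_metrics(cc)
      # independent recount from the raw prediction lists
      tp <- sum(truth & call)
      fp <- sum(!truth & call)
      tn <- sum(!truth & !call)
      fn <- sum(truth & !call)
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
      expect_equal(m$accuracy, (tp + tn) / n)
      if (m$precision + m$recall > 0) {
        expect_equal(m$f_measure, 2 * m$precision * m$recall / (m$precision + m$recall))
      }
      expect_equal(m$sn, m$recall)
      if (tn + fp > 0) expect_equal(m$sp, tn / (tn + fp))
    }
  })
})

test_that("degenerate confusion tables flag instead of erroring", {
  perfect <- compute_metrics(list(tp = 10, fp = 0, tn = 90, fn = 0))
  expect_equal(
    unlist(perfect[c("precision", "recall", "accuracy", "f_measure", "sn", "sp")]),
    rep(1, 6),
    ignore_attr = TRUE
  )
  zero_tp <- compute_metrics(list(tp = 0, fp = 5, tn = 10, fn = 3))
  expect_equal(zero_tp$precision, 0)
  expect_equal(zero_tp$f_measure, 0)
  expect_false(zero_tp$degenerate) # all denominators are positive here
  no_pred_pos <- compute_metrics(list(tp = 0, fp = 0, tn = 10, fn = 3))
  expect_true(no_pred_pos$degenerate)
  expect_error(
    compute_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
    class = "phosgram_empty_evaluation_error"
  )
})

test_that("roc_points recounts the confusion table at each threshold", {
  scores <- tibble::tibble(
    probability = c(rep(0.9, 5), rep(0.1, 20)),
    label = rep(c("positive", "negative"), c(5, 20))
  )
  pt <- roc_points(scores, grid = 0.5)
  expect_equal(pt$sn, 1)
  expect_equal(pt$fpr, 0)
  pt0 <- roc_points(scores, grid = 0)
  expect_equal(pt0$sn, 1)
  expect_equal(pt0$fpr, 1)
  expect_error(
    roc_points(tibble::tibble(probability = 0.5, label = "positive")),
    class = "phosgram_degenerate_roc_error"
  )

  withr::with_seed(47, {
    p <- stats::runif(200)
    lab <- stats::runif(200) < 0.3
    grid <- seq(0, 1, by = 0.1)
    roc <- roc_points(tibble::tibble(probability = p, label = lab), grid = grid)
    expect_true(all(diff(roc$sn) <= 0)) # sensitivity non-increasing
    for (r in seq_len(nrow(roc))) {
      cc <- confusion_counts(lab, p >= roc$threshold[r])
      m <- compute_metrics(cc)
      expect_equal(roc$sn[r], m$recall)
      expect_equal(roc$sp[r], m$sp)
    }
    # cross-check sensitivities against an established ROC implementation
    pr <- pROC::roc(response = lab, predictor = p, quiet = TRUE)
    co <- pROC::coords(pr, x = 0.5, input = "threshold", ret = c("sensitivity", "specificity"))
    # pROC thresholds are midpoints; compare at a threshold between score points
    mine <- roc_points(tibble::tibble(probability = p, label = lab), grid = 0.5)
    expect_equal(mine$sn, co$sensitivity, tolerance = 0.02)
    expect_equal(mine$sp, co$specificity, tolerance = 0.02)
  })
})

test_that("cross_validate averages per-fold metrics reproducibly", {
  pos <- generate_positives(motif_preset("PKA"), 30, seed = 1)
  neg <- generate_negatives(n = 400, seed = 2)
  learner <- alergia_learner(threshold = 1e-9)
  cv <- cross_validate(pos, neg, learner, k = 3, neg_ratio = 10, seed = 11)
  folds <- attr(cv, "folds")
  expect_equal(nrow(folds), 3)
  expect_true(all(folds$accuracy >= 0 & folds$accuracy <= 1))
  expect_equal(cv$accuracy, mean(folds$accuracy))
  cv2 <- cross_validate(pos, neg, learner, k = 3, neg_ratio = 10, seed = 11)
  expect_equal(as.data.frame(cv), as.data.frame(cv2))
  expect_error(
    cross_validate(pos[1:2, ], neg, learner, k = 3, seed = 1),
    class = "phosgram_fold_error"
  )
  expect_error(
    cross_validate(pos, neg[1:20, ], learner, k = 3, neg_ratio = 10, seed = 1),
    class = "phosgram_ratio_error"
  )
})

test_that("bootstrap resampling returns one metric row per resample, seeded", {
  pos <- generate_positives(motif_preset("PKA"), 24, seed = 3)
  neg <- generate_negatives(n = 300, seed = 4)
  learner <- alergia_learner(threshold = 1e-9)
  boot <- bootstrap_evaluate(pos, neg, learner, B = 4, k = 2, neg_ratio = 10, seed = 21)
  expect_equal(nrow(boot), 4)
  expect_equal(boot$resample, 1:4)
  boot2 <- bootstrap_evaluate(pos, neg, learner, B = 4, k = 2, neg_ratio = 10, seed = 21)
  expect_equal(as.data.frame(boot), as.data.frame(boot2))
  # resamples differ from one another (with-replacement draws change folds)
  expect_gt(stats::sd(boot$accuracy), 0)
  expect_error(
    bootstrap_evaluate(pos, neg, learner, B = 0, seed = 1),
    class = "phosgram_config_error"
  )
})

test_that("the spread of bootstrap means shrinks with more resamples", {
  # a cheap deterministic stub learner isolates the resampling behavior
  stub <- function(train_pos, train_neg) function(w) grepl("R", w)
  pos <- generate_positives(motif_preset("PKA", adherence = 0.7), 40, seed = 5)
  neg <- generate_negatives(n = 500, seed = 6)
  se_of <- function(B) {
    boot <- bootstrap_evaluate(pos, neg, stub, B = B, k = 2, neg_ratio = 5, seed = 31)
    stats::sd(boot$accuracy) / sqrt(B)
  }
  expect_lt(se_of(120), se_of(10))
})

test_that("the paired t-test matches its closed form and direction", {
  same <- paired_t_test(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 0.5)
  expect_false(same$reject)

  # differences 1, 2, 3: t = 2 / (1 / sqrt(3)), one-sided p from Student df=2
  ht <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(ht$t, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(ht$df, 2)
  expect_equal(ht$p_value, stats::pt(2 * sqrt(3), df = 2, lower.tail = FALSE))
  expect_true(ht$reject)

  worse <- paired_t_test(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.65))
  expect_lt(worse$t, 0)
  expect_false(worse$reject)

  expect_error(paired_t_test(1:3, 1:4), class = "phosgram_pairing_error")
  expect_error(paired_t_test(1, 2), class = "phosgram_sample_size_error")
})

test_that("compare_gi evaluates all learners on identical splits", {
  withr::with_seed(53, {
    ab3 <- c("A", "B", "C")
    pos <- unique(random_strings(40, ab3, max_len = 5))
    pos <- pos[nchar(pos) > 0][1:15]
    neg <- utils::head(setdiff(unique(random_strings(200, ab3, max_len = 5)), pos), 80)
    cmp <- compare_gi(pos, neg,
      learners = list(
        alergia = alergia_learner(threshold = 1e-6, alphabet = ab3),
        rpni = rpni_learner(alphabet = ab3)
      ),
      n_repeats = 3, neg_ratio = 5, seed = 61
    )
    expect_equal(nrow(cmp$metrics), 6) # 3 splits x 2 methods
    expect_equal(nrow(cmp$t_tests), 1)
    expect_equal(cmp$t_tests$comparison, "alergia vs rpni")
    expect_equal(cmp$t_tests$df, 2)
  })
})
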