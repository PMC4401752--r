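test_that("the frequency difference test matches its closed-form bound", {
  expect_false(alergia_different(25, 50, 25, 50, alpha = 0.5))
  # difference 0.8 against bound sqrt(0.5 * log(2/0.7)) * 0.2 ~ 0.145
  expect_true(alergia_different(90, 100, 10, 100, alpha = 0.7))
  # two singletons: the bound (~1.449) exceeds any achievable difference
  expect_false(alergia_different(1, 1, 0, 1, alpha = 0.7))
  expect_error(alergia_different(0, 0, 1, 2, alpha = 0.5), class = "phosgram_zero_n_error")
  expect_error(alergia_different(1, 2, 1, 2, alpha = 0), class = "phosgram_config_error")
})

test_that("decreasing alpha never turns a compatible pair incompatible", {
  withr::with_seed(5, {
    for (rep in 1:50) {
      n1 <- sample(1:200, 1)
      n2 <- sample(1:200, 1)
      f1 <- sample(0:n1, 1)
      f2 <- sample(0:n2, 1)
      alphas <- sort(stats::runif(2, 0.01, 1))
      # larger alpha -> smaller bound: differences can only appear, not vanish
      expect_true(
        alergia_different(f1, n1, f2, n2, alphas[2]) >=
          alergia_different(f1, n1, f2, n2, alphas[1])
      )
    }
  })
})

test_that("state compatibility is reflexive and matches a brute-force tree checker", {
  fa <- build_pta(fig_strings())
  expect_true(alergia_compatible(fa, 1, 1, alpha = 0.7))
  # two singleton leaves terminate with certainty: compatible
  leaves <- which(fa$f_end == fa$n & fa$n == 1L)
  expect_true(alergia_compatible(fa, leaves[1], leaves[2], alpha = 0.7))
  # oracle equivalence over all state pairs of the worked-example PTA
  for (alpha in c(0.3, 0.7)) {
    for (j in 2:n_states(fa)) {
      for (i in 1:(j - 1)) {
        expect_equal(
          alergia_compatible(fa, i, j, alpha),
          brute_compatible(fa, i, j, alpha),
          info = sprintf("pair (%d, %d), alpha %.1f", i, j, alpha)
        )
      }
    }
  }
})

test_that("merge_fold folds subtrees deterministically and conserves counts", {
  fa <- build_pta(c("AA", "A"), alphabet = c("A", "B"))
  merged <- merge_fold(fa, 2, 3)
  ids <- which(merged$alive)
  expect_equal(length(ids), 2)
  s <- setdiff(ids, merged$initial)
  expect_equal(merged$trans[[s]][["A"]], s) # self-loop
  expect_equal(merged$n[s], 3L) # 2 + 1 arrivals summed
  expect_equal(merged$f_end[s], 2L)
  expect_equal(unname(merged$counts[[s]]["A"]), 1L)

  # merging two leaves sums termination counts
  fa2 <- build_pta(c("AB", "AC"), alphabet = c("A", "B", "C"))
  leaves <- which(fa2$f_end > 0)
  m2 <- merge_fold(fa2, leaves[1], leaves[2])
  expect_equal(m2$f_end[leaves[1]], 2L)

  expect_error(merge_fold(fa, 2, 2), class = "phosgram_merge_error")
  expect_error(merge_fold(fa, 2, 1), class = "phosgram_merge_error")
})

test_that("flow conservation and the root count survive random merge sequences", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      seqs <- random_strings(25, c("A", "B"), max_len = 5)
      fa <- build_pta(seqs, alphabet = c("A", "B"))
      total <- fa$n[fa$initial]
      for (step in 1:5) {
        live <- which(fa$alive)
        live_nonroot <- setdiff(live, fa$initial)
        if (length(live_nonroot) < 1 || length(live) < 2) break
        qj <- sample(live_nonroot, 1)
        qi <- sample(setdiff(live, qj), 1)
        fa <- merge_fold(fa, qi, qj)
        # every training string still terminates exactly once
        expect_equal(sum(fa$f_end[fa$alive]), total)
        for (i in which(fa$alive)) {
          expect_equal(fa$n[i], fa$f_end[i] + sum(fa$counts[[i]]))
        }
      }
    }
  })
})

test_that("when no pair passes the test, inference returns the PTA distribution", {
  # large, clearly distinct counts at every state: no merges even at alpha = 1
  seqs <- c(rep("A", 300), rep("AB", 100))
  dsfa_nomerge <- infer_dsfa(seqs, alpha = 1, smoothing = NULL, alphabet = c("A", "B"))
  pta <- to_stochastic(build_pta(seqs, alphabet = c("A", "B")), smoothing = NULL)
  expect_equal(length(dsfa_nomerge$p_end), length(pta$p_end))
  expect_equal(dsfa_nomerge$probs, pta$probs)
  expect_equal(dsfa_nomerge$p_end, pta$p_end)
})

test_that("inference on the worked-example windows generalizes beyond the training set", {
  dsfa <- infer_dsfa(fig_strings(), alpha = 0.7, smoothing = NULL)
  p_train <- sequence_probability(dsfa, fig_strings())
  expect_true(all(p_train > 0))
  expect_lt(length(dsfa$p_end), 27) # merging actually happened
  # at least one unseen 7-mer is generated with positive unsmoothed probability
  unseen <- c(
    "RRKSACL", "RRKSCLI", "RPKSACP", "RRPSACP", "RRTSIPK",
    "RPKSPSP", "RRKSPSK"
  )
  expect_true(any(sequence_probability(dsfa, unseen) > 0))
})

test_that("a 2-state generator is recovered from simulated strings", {
  target <- two_state_target()
  ok <- 0L
  for (seed in 1:3) {
    seqs <- withr::with_seed(seed, sample_from_dsfa(target, 1500))
    learned <- infer_dsfa(seqs, alpha = 0.05, smoothing = NULL, alphabet = c("A", "B"))
    if (recovered_two_state(learned, tol = 0.05)) ok <- ok + 1L
  }
  expect_gte(ok, 2)
})

test_that("inference is deterministic for a fixed input order and config", {
  seqs <- withr::with_seed(9, sample_from_dsfa(two_state_target(), 300))
  m1 <- infer_dsfa(seqs, alpha = 0.2, alphabet = c("A", "B"))
  m2 <- infer_dsfa(seqs, alpha = 0.2, alphabet = c("A", "B"))
  expect_identical(m1$probs, m2$probs)
  expect_identical(m1$trans, m2$trans)
})
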