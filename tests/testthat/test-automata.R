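test_that("build_pta creates one state per distinct prefix with threaded counts", {
  fa <- build_pta(fig_strings())
  expect_equal(n_states(fa), 27) # root + 26 distinct nonempty prefixes
  expect_equal(fa$n[fa$initial], 5L)

  chain <- build_pta("ACD", alphabet = c("A", "C", "D"))
  expect_equal(n_states(chain), 4)
  expect_equal(chain$n, c(1L, 1L, 1L, 1L))
  expect_equal(chain$f_end, c(0L, 0L, 0L, 1L))

  expect_error(build_pta(character(0)), class = "phosgram_empty_input_error")
  expect_error(
    build_pta("AB1", alphabet = c("A", "B")),
    class = "phosgram_alphabet_error"
  )
})

test_that("flow conservation holds at every PTA state", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      seqs <- random_strings(30, c("A", "B", "C"), max_len = 6)
      seqs <- seqs[nchar(seqs) > 0]
      if (length(seqs) == 0) next
      fa <- build_pta(seqs, alphabet = c("A", "B", "C"))
      for (i in which(fa$alive)) {
        expect_equal(fa$n[i], fa$f_end[i] + sum(fa$counts[[i]]))
      }
    }
  })
})

test_that("build_pta is order-insensitive up to the standard-order numbering", {
  withr::with_seed(3, {
    seqs <- random_strings(25, c("A", "B"), max_len = 5)
    fa1 <- build_pta(seqs, alphabet = c("A", "B"))
    fa2 <- build_pta(sample(seqs), alphabet = c("A", "B"))
    expect_identical(fa1$n, fa2$n)
    expect_identical(fa1$f_end, fa2$f_end)
    expect_identical(fa1$trans, fa2$trans)
    expect_identical(fa1$counts, fa2$counts)
  })
})

test_that("to_stochastic computes maximum-likelihood transition probabilities", {
  dsfa <- to_stochastic(build_pta(fig_strings()), smoothing = NULL)
  # at the root every string starts with R; at state "R", 4 of 5 continue with R
  expect_equal(unname(dsfa$probs[[1]]["R"]), 1.0)
  state_r <- dsfa$trans[[1]][["R"]]
  expect_equal(unname(dsfa$probs[[state_r]]["R"]), 0.8)

  single <- to_stochastic(build_pta("AC", alphabet = c("A", "C")), smoothing = NULL)
  expect_equal(sequence_probability(single, "AC"), 1)
  expect_equal(single$p_end[length(single$p_end)], 1)
})

test_that("each training string has probability multiplicity/N and the total is 1", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      seqs <- random_strings(40, c("A", "B"), max_len = 5)
      dsfa <- to_stochastic(build_pta(seqs, alphabet = c("A", "B")), smoothing = NULL)
      tab <- table(seqs)
      p <- sequence_probability(dsfa, names(tab))
      expect_equal(p, unname(as.vector(tab)) / length(seqs), ignore_attr = TRUE)
      expect_equal(sum(p), 1)
    }
  })
})

test_that("the per-state normalization identity holds for unsmoothed automata", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      seqs <- random_strings(30, c("A", "B", "C"), max_len = 6)
      dsfa <- to_stochastic(build_pta(seqs, alphabet = c("A", "B", "C")), smoothing = NULL)
      expect_lt(stochastic_residual(dsfa), 1e-9)
    }
  })
})

test_that("smoothing floors zero termination probabilities at scoring time", {
  # every training string continues past "A", so the state after "A" has
  # f_end = 0; a string stopping there must pick up the 0.01 floor
  dsfa <- to_stochastic(build_pta(c("AB", "AC"), alphabet = c("A", "B", "C")),
    smoothing = 0.01
  )
  expect_equal(sequence_probability(dsfa, "A"), 1 * 0.01)
  expect_equal(sequence_probability(dsfa, "A", smoothed = FALSE), 0)
  # an unseen symbol path contributes the floor per missing step
  expect_equal(sequence_probability(dsfa, "CC"), 0.01 * 0.01 * 0.01)
})

test_that("JSON serialization round-trips a learned model losslessly", {
  model <- infer_dsfa(fig_strings(), alpha = 0.7, smoothing = 0.01)
  model$meta$flank <- 3
  path <- withr::local_tempfile(fileext = ".json")
  write_dsfa(model, path)
  back <- read_dsfa(path)
  expect_equal(back$p_end, model$p_end)
  expect_equal(back$trans, model$trans)
  expect_equal(back$probs, model$probs)
  expect_equal(back$smoothing, model$smoothing)
  expect_equal(back$meta$alpha, model$meta$alpha)
  probe <- c(fig_strings(), "AAAAAAA", "RRKSACL")
  expect_equal(
    sequence_probability(back, probe),
    sequence_probability(model, probe)
  )
})

test_that("DOT export lists every state and labelled transition", {
  dsfa <- to_stochastic(build_pta(c("AB", "AA"), alphabet = c("A", "B")), smoothing = NULL)
  dot <- automaton_dot(dsfa)
  expect_match(dot, "digraph")
  expect_equal(length(gregexpr("->", dot)[[1]]), sum(lengths(dsfa$trans)))
  path <- withr::local_tempfile(fileext = ".dot")
  automaton_dot(dsfa, path)
  expect_identical(paste(readLines(path), collapse = "\n"), dot)
})

test_that("tidy and glance summarize automata", {
  fa <- build_pta(fig_strings())
  dsfa <- to_stochastic(fa, smoothing = NULL)
  td <- generics::tidy(dsfa)
  expect_equal(nrow(td), sum(lengths(dsfa$trans)))
  expect_true(all(td$probability > 0 & td$probability <= 1))
  gl <- generics::glance(dsfa)
  expect_equal(gl$n_states, 27)
  expect_lt(gl$normalization_residual, 1e-12)
  expect_equal(generics::glance(fa)$n_training, 5L)
})
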