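#' Run strings through a plain accept/reject DFA
#'
#' A string is accepted when the simulation consumes every symbol along
#' defined transitions and ends in an accepting state; an undefined transition
#' rejects.
#'
#' @param dfa A `dfa` object.
#' @param strings Character vector.
#' @return Logical vector.
#' @export
dfa_accepts <- function(dfa, strings) {
  stopifnot(inherits(dfa, "dfa"))
  syms_list <- split_symbols(strings, dfa$alphabet)
  vapply(syms_list, function(syms) {
    cur <- dfa$initial
    for (a in syms) {
      nxt <- dfa$trans[[cur]][a]
      if (is.na(nxt)) return(FALSE)
      cur <- nxt[[1]]
    }
    dfa$accepting[cur]
  }, logical(1))
}

# convert a frequency automaton to a plain DFA (accepting = nonzero
# termination count), renumbered to standard order
as_dfa <- function(fa) {
  fa <- renumber_standard(fa)
  structure(
    list(
      alphabet = fa$alphabet, initial = 1L,
      trans = fa$trans, accepting = fa$f_end > 0L,
      meta = list()
    ),
    class = "dfa"
  )
}

#' RPNI: DFA inference from positive and negative strings
#'
#' Regular positive and negative inference. Builds the prefix tree acceptor
#' of the positives, numbers its states in standard order, and for each state
#' in ascending order attempts to merge it with every lower-numbered state,
#' keeping the (determinized) quotient automaton only when it still rejects
#' every negative string. The result accepts all positives and rejects all
#' negatives, and never has more states than the PTA.
#'
#' @param positives,negatives Character vectors (or windows data frames) of
#'   accepted / rejected strings; they must be disjoint.
#' @param alphabet Symbol set.
#' @return A `dfa` object.
#' @export
#' @examples
#' m <- rpni("A", "B", alphabet = c("A", "B"))
#' dfa_accepts(m, c("A", "B"))
rpni <- function(positives, negatives, alphabet = aa_alphabet()) {
  pos <- window_strings(positives, "positives")
  neg <- window_strings(negatives, "negatives")
  if (length(pos) == 0) {
    abort("positives are empty", class = "phosgram_empty_input_error")
  }
  both <- intersect(pos, neg)
  if (length(both) > 0) {
    abort(
      sprintf("inconsistent sample: %s in both sets", paste(both, collapse = ", ")),
      class = "phosgram_inconsistent_sample_error"
    )
  }
  split_symbols(neg, alphabet) # validate negatives against the alphabet too
  fa <- build_pta(pos, alphabet = alphabet)
  j <- 2L
  while (j <= length(fa$n)) {
    if (fa$alive[j]) {
      for (i in seq_len(j - 1L)) {
        if (!fa$alive[i]) next
        cand <- quotient_merge(fa, list(c(i, j)))
        if (!any(freq_accepts(cand, neg))) {
          fa <- cand
          break
        }
      }
    }
    j <- j + 1L
  }
  out <- as_dfa(fa)
  out$meta <- list(method = "rpni", n_pos = length(pos), n_neg = length(neg))
  out
}

#' Genetic-algorithm configuration
#'
#' @param population_size Individuals per generation (>= 1).
#' @param generations Number of generations (>= 0).
#' @param mutation_rate Per-individual probability of moving one state to a
#'   random block.
#' @param crossover_rate Probability that a selected pair recombines by
#'   single-point block exchange.
#' @param state_weight,error_weight Non-negative fitness weights on the state
#'   count and on misclassified negatives (see [ga_fitness()]).
#' @param elitism Number of top individuals copied unchanged each generation.
#' @param seed Integer seed.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, generations = 100,
                      mutation_rate = 0.05, crossover_rate = 0.8,
                      state_weight = 1, error_weight = 10,
                      elitism = 1, seed = NULL) {
  if (population_size < 1) {
    abort("population_size must be >= 1", class = "phosgram_config_error")
  }
  if (generations < 0) {
    abort("generations must be >= 0", class = "phosgram_config_error")
  }
  if (mutation_rate < 0 || mutation_rate > 1 || crossover_rate < 0 || crossover_rate > 1) {
    abort("rates must be in [0, 1]", class = "phosgram_config_error")
  }
  structure(
    list(
      population_size = as.integer(population_size),
      generations = as.integer(generations),
      mutation_rate = mutation_rate, crossover_rate = crossover_rate,
      state_weight = state_weight, error_weight = error_weight,
      elitism = as.integer(elitism), seed = seed
    ),
    class = "ga_config"
  )
}

#' Fitness of a quotient automaton
#'
#' Individuals with fewer states and fewer misclassified negatives are fitter:
#' `-(state_weight * n_states + error_weight * errors)`.
#'
#' @param n_states Number of states of the quotient automaton.
#' @param errors Number of negative strings it wrongly accepts.
#' @param state_weight,error_weight Non-negative weights.
#' @return A (non-positive) fitness value; larger is better.
#' @export
ga_fitness <- function(n_states, errors, state_weight = 1, error_weight = 10) {
  -(state_weight * n_states + error_weight * errors)
}

#' Quotient automaton of a state partition
#'
#' Merges every block of the partition to a single state and closes the result
#' under determinism (blocks forced together by a shared outgoing symbol are
#' merged as well), so the returned automaton is always a valid member of the
#' lattice of quotients of the input.
#'
#' @param fa A `freq_automaton` (typically a PTA).
#' @param assignment Integer vector, one block id per state of `fa`.
#' @return A `freq_automaton` (counts summed blockwise).
#' @export
quotient_automaton <- function(fa, assignment) {
  stopifnot(inherits(fa, "freq_automaton"), length(assignment) == length(fa$n))
  groups <- split(seq_along(assignment), assignment)
  groups <- groups[lengths(groups) > 1]
  quotient_merge(fa, unname(groups))
}

#' Infer a DFA by a genetic-algorithm search over PTA state partitions
#'
#' Builds the PTA of the positives and evolves a population of random state
#' partitions. Each individual is evaluated as the determinized quotient
#' automaton of its partition, with fitness [ga_fitness()] (fewer states,
#' fewer accepted negatives). Selection is fitness-proportionate, offspring
#' arise by single-point block-exchange crossover and point mutation (moving
#' one state to a random block), and the configured elite survives unchanged
#' so the best fitness never decreases. Reproducible for a fixed seed.
#'
#' @param positives,negatives Character vectors (or windows data frames).
#' @param config A [ga_config()].
#' @param alphabet Symbol set.
#' @return A `dfa`; `attr(, "fitness")` holds the winning fitness and
#'   `attr(, "trajectory")` the best fitness per generation.
#' @export
ga_infer <- function(positives, negatives, config = ga_config(),
                     alphabet = aa_alphabet()) {
  stopifnot(inherits(config, "ga_config"))
  pos <- window_strings(positives, "positives")
  neg <- window_strings(negatives, "negatives")
  if (length(pos) == 0) {
    abort("positives are empty", class = "phosgram_empty_input_error")
  }
  split_symbols(neg, alphabet)
  pta <- build_pta(pos, alphabet = alphabet)
  t <- length(pta$n)

  evaluate <- function(assignment) {
    q <- quotient_automaton(pta, assignment)
    s <- sum(q$alive)
    e <- sum(freq_accepts(q, neg))
    list(
      quotient = q,
      fitness = ga_fitness(s, e, config$state_weight, config$error_weight)
    )
  }

  with_seed_(config$seed, {
    pop <- replicate(config$population_size,
      sample.int(t, t, replace = TRUE),
      simplify = FALSE
    )
    evals <- lapply(pop, evaluate)
    fit <- vapply(evals, `[[`, numeric(1), "fitness")
    trajectory <- numeric(config$generations)
    gen <- 0L
    while (gen < config$generations) {
      gen <- gen + 1L
      ord <- order(fit, decreasing = TRUE)
      elite_idx <- ord[seq_len(min(config$elitism, length(pop)))]
      # fitness-proportionate selection on shifted fitness
      w <- fit - min(fit) + 1
      pick <- function() pop[[sample.int(length(pop), 1, prob = w)]]
      children <- lapply(seq_len(config$population_size - length(elite_idx)), function(k) {
        a <- pick()
        b <- pick()
        child <- if (stats::runif(1) < config$crossover_rate && t > 1) {
          cut <- sample.int(t - 1, 1)
          c(a[seq_len(cut)], b[(cut + 1):t])
        } else {
          a
        }
        if (stats::runif(1) < config$mutation_rate) {
          child[sample.int(t, 1)] <- sample.int(t, 1)
        }
        # repair: canonical block numbering keeps every state in exactly one block
        as.integer(factor(child, levels = unique(child)))
      })
      pop <- c(pop[elite_idx], children)
      evals <- c(evals[elite_idx], lapply(children, evaluate))
      fit <- vapply(evals, `[[`, numeric(1), "fitness")
      trajectory[gen] <- max(fit)
    }
    best <- evals[[which.max(fit)]]
    out <- as_dfa(best$quotient)
    out$meta <- list(method = "ga", n_pos = length(pos), n_neg = length(neg))
    attr(out, "fitness") <- best$fitness
    attr(out, "trajectory") <- trajectory
    out
  })
}
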