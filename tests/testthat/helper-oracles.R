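# Independent oracles and generators used across the suite.
# These deliberately avoid the package's path-product implementation.

# state-vector recursion for the probability that a stochastic automaton
# generates string w: propagate mass through the transition matrices symbol by
# symbol, then weight by the final-state probabilities
oracle_probability <- function(dsfa, w) {
  n <- length(dsfa$p_end)
  v <- numeric(n)
  v[dsfa$initial] <- 1
  syms <- if (nchar(w) == 0) character(0) else strsplit(w, "")[[1]]
  for (a in syms) {
    v2 <- numeric(n)
    for (i in which(v > 0)) {
      j <- dsfa$trans[[i]][a]
      if (!is.na(j)) v2[j[[1]]] <- v2[j[[1]]] + v[i] * dsfa$probs[[i]][[a]]
    }
    v <- v2
  }
  sum(v * dsfa$p_end)
}

# emission probability of the k-th symbol of w via the state-distribution
# recursion (point mass for deterministic machines, but derived independently)
oracle_emission <- function(dsfa, w, k) {
  n <- length(dsfa$p_end)
  v <- numeric(n)
  v[dsfa$initial] <- 1
  syms <- strsplit(w, "")[[1]]
  for (a in syms[seq_len(k - 1)]) {
    v2 <- numeric(n)
    for (i in which(v > 0)) {
      j <- dsfa$trans[[i]][a]
      if (!is.na(j)) v2[j[[1]]] <- v2[j[[1]]] + v[i] * dsfa$probs[[i]][[a]]
    }
    v <- v2
  }
  if (sum(v) == 0) return(0)
  a <- syms[k]
  num <- sum(vapply(which(v > 0), function(i) {
    p <- dsfa$probs[[i]][a]
    v[i] * (if (is.na(p)) 0 else p)
  }, numeric(1)))
  num / sum(v)
}

# random deterministic stochastic automaton satisfying the per-state
# normalization identity by construction
random_dsfa <- function(n_states, alphabet = c("A", "B")) {
  trans <- vector("list", n_states)
  probs <- vector("list", n_states)
  p_end <- numeric(n_states)
  for (i in seq_len(n_states)) {
    present <- alphabet[stats::runif(length(alphabet)) < 0.7]
    w <- stats::rexp(length(present) + 1)
    w <- w / sum(w)
    p_end[i] <- w[1]
    if (length(present) > 0) {
      trans[[i]] <- stats::setNames(sample.int(n_states, length(present), replace = TRUE), present)
      probs[[i]] <- stats::setNames(w[-1], present)
    } else {
      trans[[i]] <- integer(0)
      probs[[i]] <- numeric(0)
    }
  }
  structure(
    list(
      alphabet = alphabet, initial = 1L, trans = trans, probs = probs,
      p_end = p_end, n = rep(1L, n_states), f_end = rep(0L, n_states),
      counts = lapply(probs, function(p) stats::setNames(rep(0L, length(p)), names(p))),
      smoothing = NA_real_, meta = list()
    ),
    class = "dsfa"
  )
}

# simulate strings from a stochastic automaton
sample_from_dsfa <- function(dsfa, n, max_len = 200) {
  vapply(seq_len(n), function(k) {
    cur <- dsfa$initial
    out <- character(0)
    while (length(out) < max_len) {
      syms <- names(dsfa$probs[[cur]])
      p <- c(dsfa$p_end[cur], unname(dsfa$probs[[cur]]))
      pick <- sample.int(length(p), 1, prob = p)
      if (pick == 1) break
      a <- syms[pick - 1]
      out <- c(out, a)
      cur <- dsfa$trans[[cur]][a][[1]]
    }
    paste(out, collapse = "")
  }, character(1))
}

# the documented 2-state target used by the parameter-recovery study
two_state_target <- function() {
  structure(
    list(
      alphabet = c("A", "B"), initial = 1L,
      trans = list(c(A = 2L, B = 1L), c(A = 1L, B = 2L)),
      probs = list(c(A = 0.4, B = 0.3), c(A = 0.2, B = 0.5)),
      p_end = c(0.3, 0.3),
      n = c(1L, 1L), f_end = c(0L, 0L),
      counts = list(c(A = 0L, B = 0L), c(A = 0L, B = 0L)),
      smoothing = NA_real_, meta = list()
    ),
    class = "dsfa"
  )
}

# check the recovered automaton against the target: exactly two states, and
# each parameter of the initial state / its A-successor within `tol` of truth
recovered_two_state <- function(dsfa, tol = 0.05) {
  if (length(dsfa$p_end) != 2) return(FALSE)
  target <- two_state_target()
  p_of <- function(i, a) {
    p <- dsfa$probs[[i]][a]
    if (is.na(p)) 0 else unname(p)
  }
  s2 <- dsfa$trans[[1]]["A"]
  if (is.na(s2)) return(FALSE)
  s2 <- s2[[1]]
  ok1 <- abs(p_of(1, "A") - 0.4) < tol && abs(p_of(1, "B") - 0.3) < tol &&
    abs(dsfa$p_end[1] - 0.3) < tol
  ok2 <- abs(p_of(s2, "A") - 0.2) < tol && abs(p_of(s2, "B") - 0.5) < tol &&
    abs(dsfa$p_end[s2] - 0.3) < tol
  ok1 && ok2 && s2 != 1
}

# independent recursive compatibility checker, valid on tree-shaped automata
# (a PTA before any merge); no memoization, no cycle handling
brute_compatible <- function(fa, qi, qj, alpha) {
  bound <- function(n1, n2) sqrt(0.5 * log(2 / alpha)) * (1 / sqrt(n1) + 1 / sqrt(n2))
  rec <- function(i, j) {
    if (is.na(i) || is.na(j)) return(TRUE) # absent successor: zero-count state
    ni <- fa$n[i]
    nj <- fa$n[j]
    if (abs(fa$f_end[i] / ni - fa$f_end[j] / nj) > bound(ni, nj)) return(FALSE)
    for (a in fa$alphabet) {
      fi <- fa$counts[[i]][a]
      fj <- fa$counts[[j]][a]
      fi <- if (is.na(fi)) 0 else fi
      fj <- if (is.na(fj)) 0 else fj
      if (abs(fi / ni - fj / nj) > bound(ni, nj)) return(FALSE)
      ci <- fa$trans[[i]][a]
      cj <- fa$trans[[j]][a]
      if (!is.na(ci) && !is.na(cj) && !rec(ci[[1]], cj[[1]])) return(FALSE)
    }
    TRUE
  }
  if (qi == qj) return(TRUE)
  rec(qi, qj)
}

# all strings of exactly length n over an alphabet
enumerate_strings <- function(alphabet, n) {
  if (n == 0) return("")
  grids <- rep(list(alphabet), n)
  apply(expand.grid(grids, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

# random strings over an alphabet with geometric-ish lengths
random_strings <- function(n, alphabet, max_len = 8) {
  vapply(seq_len(n), function(k) {
    len <- sample.int(max_len + 1, 1) - 1L
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# the five worked-example training 7-mers
fig_strings <- function() c("RRKSACP", "RRKSIPK", "RRPSCAL", "RRTSCLI", "RPKSPSK")
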