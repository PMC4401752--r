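#' Build a prefix tree acceptor (PTA) with Alergia frequency counts
#'
#' The PTA is a tree-shaped deterministic automaton with one state per distinct
#' prefix of the training set (the root is the empty prefix). Threading each
#' training string from the root to a leaf populates the frequency estimates
#' used by Alergia: `n[i]`, the number of strings arriving at state `i`;
#' `counts[[i]][a]`, the number of strings leaving state `i` on symbol `a`; and
#' `f_end[i]`, the number of strings ending at state `i`. Flow conservation
#' `n[i] == f_end[i] + sum(counts[[i]])` holds at every state, and the PTA
#' accepts exactly the training multiset.
#'
#' States are numbered in standard order: breadth-first from the root, children
#' visited in alphabetical symbol order. This makes serialized models and the
#' RPNI/Alergia pair scans reproducible.
#'
#' @param x Training strings: a character vector or a windows data frame with a
#'   `window` column.
#' @param alphabet Symbol set; defaults to [aa_alphabet()].
#' @return A `freq_automaton` object.
#' @export
#' @examples
#' fa <- build_pta(c("RRKSACP", "RRKSIPK"))
#' fa
build_pta <- function(x, alphabet = aa_alphabet()) {
  sequences <- window_strings(x)
  if (length(sequences) == 0) {
    abort("training set is empty", class = "phosgram_empty_input_error")
  }
  syms_list <- split_symbols(sequences, alphabet)

  trans <- list(integer(0))
  counts <- list(integer(0))
  n <- 0L
  f_end <- 0L
  nst <- 1L
  for (syms in syms_list) {
    cur <- 1L
    n[cur] <- n[cur] + 1L
    for (a in syms) {
      tr <- trans[[cur]]
      if (is.na(tr[a])) {
        nst <- nst + 1L
        trans[[nst]] <- integer(0)
        counts[[nst]] <- integer(0)
        n[nst] <- 0L
        f_end[nst] <- 0L
        trans[[cur]][a] <- nst
        counts[[cur]][a] <- 0L
      }
      counts[[cur]][a] <- counts[[cur]][a] + 1L
      cur <- trans[[cur]][a]
      n[cur] <- n[cur] + 1L
    }
    f_end[cur] <- f_end[cur] + 1L
  }

  fa <- structure(
    list(
      alphabet = alphabet, initial = 1L,
      n = n, f_end = f_end, trans = trans, counts = counts,
      alive = rep(TRUE, nst)
    ),
    class = "freq_automaton"
  )
  renumber_standard(fa)
}

# renumber states breadth-first with alphabetically sorted symbols and drop
# dead states; initial becomes state 1
renumber_standard <- function(fa) {
  nst <- length(fa$n)
  ord <- integer(0)
  seen <- logical(nst)
  queue <- fa$initial
  seen[fa$initial] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, cur)
    tr <- fa$trans[[cur]]
    for (a in sort(names(tr))) {
      ch <- tr[[a]]
      if (!seen[ch]) {
        seen[ch] <- TRUE
        queue <- c(queue, ch)
      }
    }
  }
  newid <- integer(nst)
  newid[ord] <- seq_along(ord)
  out <- fa
  out$n <- fa$n[ord]
  out$f_end <- fa$f_end[ord]
  out$alive <- rep(TRUE, length(ord))
  # canonical form: symbols sorted alphabetically within each state
  sort_by_name <- function(x) if (length(x) == 0) x else x[order(names(x))]
  out$trans <- lapply(ord, function(i) {
    tr <- sort_by_name(fa$trans[[i]])
    setNames(newid[tr], names(tr))
  })
  out$counts <- lapply(ord, function(i) sort_by_name(fa$counts[[i]]))
  out$initial <- 1L
  out
}

#' Number of live states in an automaton
#'
#' @param x A `freq_automaton`, `dsfa` or `dfa` object.
#' @return Integer count of states.
#' @export
n_states <- function(x) {
  if (inherits(x, "freq_automaton")) return(sum(x$alive))
  length(x$n %||% x$p_end %||% x$accepting)
}

# check flow conservation n_i = f_end_i + sum_a f_i(a) at every live state
validate_flow <- function(fa) {
  ids <- which(fa$alive)
  ok <- vapply(
    ids,
    function(i) fa$n[i] == fa$f_end[i] + sum(fa$counts[[i]]),
    logical(1)
  )
  if (!all(ok)) {
    abort(
      sprintf("flow conservation violated at state(s) %s", paste(ids[!ok], collapse = ", ")),
      class = "phosgram_flow_error"
    )
  }
  invisible(fa)
}

#' Convert a frequency automaton to a stochastic automaton (DSFA)
#'
#' Transition probabilities are the maximum-likelihood estimates
#' `P[i -> j on a] = f_i(a) / n_i` along existing transitions and the
#' final-state probability is `P_if = f_i(#) / n_i`, so at every state the
#' final probability plus all outgoing transition probabilities sums to 1.
#'
#' `smoothing` stores a floor applied at *lookup* time during scoring: any
#' zero transition or termination probability consulted while scoring a window
#' contributes the smoothing value instead (default 0.01). The stored
#' parameters themselves are not renormalized, so the per-state normalization
#' identity is a property of the unsmoothed parameters only.
#'
#' @param fa A `freq_automaton`.
#' @param smoothing Probability floor used at scoring time, or `NULL` for a
#'   strictly unsmoothed automaton.
#' @return A `dsfa` object.
#' @export
#' @examples
#' dsfa <- to_stochastic(build_pta(c("AB", "AC"), alphabet = c("A", "B", "C")), smoothing = NULL)
#' sequence_probability(dsfa, "AB")
to_stochastic <- function(fa, smoothing = 0.01) {
  stopifnot(inherits(fa, "freq_automaton"))
  validate_flow(fa)
  fa <- renumber_standard(fa)
  if (any(fa$n == 0)) {
    abort("reachable state with zero arrival count", class = "phosgram_counts_error")
  }
  if (!is.null(smoothing) && (smoothing < 0 || smoothing >= 1)) {
    abort("smoothing must be in [0, 1)", class = "phosgram_config_error")
  }
  probs <- lapply(seq_along(fa$n), function(i) fa$counts[[i]] / fa$n[i])
  structure(
    list(
      alphabet = fa$alphabet, initial = 1L,
      trans = fa$trans, probs = probs,
      p_end = fa$f_end / fa$n,
      n = fa$n, f_end = fa$f_end, counts = fa$counts,
      smoothing = if (is.null(smoothing)) NA_real_ else smoothing,
      meta = list()
    ),
    class = "dsfa"
  )
}

#' Per-state normalization residual of a stochastic automaton
#'
#' For every state of an unsmoothed DSFA the final probability plus the sum of
#' outgoing transition probabilities must equal 1. This returns the largest
#' absolute deviation from that identity across states, useful as a model
#' sanity check (it is 0 up to floating-point error for any automaton produced
#' by [to_stochastic()]).
#'
#' @param dsfa A `dsfa` object.
#' @return A single non-negative number.
#' @export
stochastic_residual <- function(dsfa) {
  stopifnot(inherits(dsfa, "dsfa"))
  out <- vapply(
    seq_along(dsfa$p_end),
    function(i) abs(dsfa$p_end[i] + sum(dsfa$probs[[i]]) - 1),
    numeric(1)
  )
  max(out)
}

## ---- union-find quotient with determinization closure --------------------

# Merge groups of states of a frequency automaton into single states.
# `unions` is a list of integer vectors; all states within a vector are
# identified. Afterwards the quotient is closed under determinism: whenever a
# block has two outgoing transitions on the same symbol into different blocks,
# those target blocks are merged too (the classic fold). Counts (n, f_end,
# per-symbol) are summed over block members, so flow conservation is preserved.
quotient_merge <- function(fa, unions) {
  unions <- lapply(unions, as.integer)
  nst <- length(fa$n)
  parent <- seq_len(nst)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  unite <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (grp in unions) {
    for (k in seq_along(grp)[-1]) unite(grp[1], grp[k])
  }
  # determinization closure
  repeat {
    changed <- FALSE
    target <- new.env(parent = emptyenv())
    for (s in which(fa$alive)) {
      b <- find(s)
      tr <- fa$trans[[s]]
      for (k in seq_along(tr)) {
        key <- paste0(b, ".", names(tr)[k])
        tb <- find(tr[[k]])
        prev <- target[[key]]
        if (is.null(prev)) {
          target[[key]] <- tb
        } else if (prev != tb) {
          unite(prev, tb)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # rebuild blockwise
  out <- fa
  live <- which(fa$alive)
  roots <- vapply(live, find, integer(1))
  for (i in live) {
    r <- find(i)
    if (r != i) {
      out$n[r] <- out$n[r] + fa$n[i]
      out$f_end[r] <- out$f_end[r] + fa$f_end[i]
      out$alive[i] <- FALSE
    }
  }
  for (r in unique(roots)) {
    members <- live[roots == r]
    tr <- integer(0)
    ct <- integer(0)
    for (m in members) {
      trm <- fa$trans[[m]]
      for (k in seq_along(trm)) {
        a <- names(trm)[k]
        prev <- ct[a]
        ct[a] <- (if (is.na(prev)) 0L else prev) + fa$counts[[m]][[a]]
        tr[a] <- find(trm[[k]])
      }
    }
    out$trans[[r]] <- tr
    out$counts[[r]] <- ct
  }
  out$initial <- find(fa$initial)
  out
}

#' Merge one automaton state into another, folding their subtrees
#'
#' Identifies state `qj` with state `qi` and recursively identifies any pair of
#' successor states reached on the same symbol, so the result stays
#' deterministic. All frequency counts (`n`, per-symbol, termination) are
#' summed across identified states, so flow conservation and the total
#' training-string count at the initial state are preserved.
#'
#' @param fa A `freq_automaton`.
#' @param qi,qj Distinct live state ids; `qj` must not be the initial state
#'   (the initial state is never folded away).
#' @return A new `freq_automaton`.
#' @export
#' @examples
#' fa <- build_pta(c("AA", "A"), alphabet = c("A", "B"))
#' merged <- merge_fold(fa, 2, 3) # self-loop on A at state 2
merge_fold <- function(fa, qi, qj) {
  stopifnot(inherits(fa, "freq_automaton"))
  if (qi == qj) {
    abort("cannot merge a state with itself", class = "phosgram_merge_error")
  }
  if (qj == fa$initial) {
    abort("cannot fold the initial state into a descendant", class = "phosgram_merge_error")
  }
  if (!fa$alive[qi] || !fa$alive[qj]) {
    abort("both states must be live", class = "phosgram_merge_error")
  }
  quotient_merge(fa, list(c(qi, qj)))
}

# run a set of strings through a frequency automaton; accepted iff every
# transition is defined and the end state has a nonzero termination count
freq_accepts <- function(fa, strings) {
  syms_list <- split_symbols(strings, fa$alphabet)
  vapply(syms_list, function(syms) {
    cur <- fa$initial
    for (a in syms) {
      nxt <- fa$trans[[cur]][a]
      if (is.na(nxt)) return(FALSE)
      cur <- nxt[[1]]
    }
    fa$f_end[cur] > 0L
  }, logical(1))
}

## ---- printing -------------------------------------------------------------

#' @export
print.freq_automaton <- function(x, ...) {
  cat(sprintf(
    "<freq_automaton: %d states, %d training strings, alphabet size %d>\n",
    sum(x$alive), x$n[x$initial], length(x$alphabet)
  ))
  invisible(x)
}

#' @export
print.dsfa <- function(x, ...) {
  sm <- if (is.na(x$smoothing)) "unsmoothed" else sprintf("smoothing %g", x$smoothing)
  cat(sprintf(
    "<dsfa: %d states, alphabet size %d, %s>\n",
    length(x$p_end), length(x$alphabet), sm
  ))
  if (!is.null(x$meta$alpha)) {
    cat(sprintf("  inferred by Alergia, alpha = %g\n", x$meta$alpha))
  }
  invisible(x)
}

#' @export
print.dfa <- function(x, ...) {
  cat(sprintf(
    "<dfa: %d states, %d accepting, alphabet size %d>\n",
    length(x$accepting), sum(x$accepting), length(x$alphabet)
  ))
  invisible(x)
}
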