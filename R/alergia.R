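#' Hoeffding-style frequency difference test
#'
#' Two observed frequencies `f1/n1` and `f2/n2` are declared *different* when
#' their gap exceeds the confidence bound
#' `sqrt(0.5 * log(2 / alpha)) * (1 / sqrt(n1) + 1 / sqrt(n2))`.
#' Larger `alpha` shrinks the bound (a stricter test, so fewer state merges);
#' smaller `alpha` tolerates larger sampling fluctuations.
#'
#' @param f1,n1,f2,n2 Success and trial counts of the two samples; `n1`, `n2`
#'   must be positive.
#' @param alpha Confidence parameter in (0, 1].
#' @return Logical (vectorized over the count arguments).
#' @export
#' @examples
#' alergia_different(90, 100, 10, 100, alpha = 0.7) # TRUE
#' alergia_different(1, 1, 0, 1, alpha = 0.7) # FALSE: bound exceeds 1
alergia_different <- function(f1, n1, f2, n2, alpha) {
  if (alpha <= 0 || alpha > 1) {
    abort("alpha must be in (0, 1]", class = "phosgram_config_error")
  }
  if (any(n1 <= 0) || any(n2 <= 0)) {
    abort("frequencies are undefined for zero trials", class = "phosgram_zero_n_error")
  }
  bound <- sqrt(0.5 * log(2 / alpha)) * (1 / sqrt(n1) + 1 / sqrt(n2))
  abs(f1 / n1 - f2 / n2) > bound
}

#' Statistical compatibility of two automaton states
#'
#' States are compatible when their termination frequencies are not
#' [alergia_different()], their outgoing frequencies agree for every symbol,
#' and every pair of same-symbol successors is recursively compatible. A
#' missing successor acts as a zero-count state, which is compatible with
#' anything (its confidence bound is unbounded). On merged (cyclic) automata
#' a revisited state pair is taken as compatible, the usual coinductive
#' reading.
#'
#' @param fa A `freq_automaton`.
#' @param qi,qj Live state ids.
#' @param alpha Confidence parameter in (0, 1].
#' @return `TRUE` or `FALSE`.
#' @export
alergia_compatible <- function(fa, qi, qj, alpha) {
  stopifnot(inherits(fa, "freq_automaton"))
  seen <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == j) return(TRUE)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(seen[[key]])) return(TRUE)
    seen[[key]] <- TRUE
    ni <- fa$n[i]
    nj <- fa$n[j]
    if (ni == 0L || nj == 0L) return(TRUE)
    if (alergia_different(fa$f_end[i], ni, fa$f_end[j], nj, alpha)) return(FALSE)
    for (a in union(names(fa$trans[[i]]), names(fa$trans[[j]]))) {
      fi <- fa$counts[[i]][a]
      if (is.na(fi)) fi <- 0L
      fj <- fa$counts[[j]][a]
      if (is.na(fj)) fj <- 0L
      if (alergia_different(fi, ni, fj, nj, alpha)) return(FALSE)
      ci <- fa$trans[[i]][a]
      cj <- fa$trans[[j]][a]
      if (!is.na(ci) && !is.na(cj) && !rec(ci[[1]], cj[[1]])) return(FALSE)
    }
    TRUE
  }
  rec(qi, qj)
}

#' Infer a stochastic automaton from positive windows with Alergia
#'
#' Builds the prefix tree acceptor of the training windows, then repeatedly
#' scans ordered state pairs (`j` ascending from the second state, `i`
#' ascending below `j`) and folds together the first compatible pair, until a
#' full pass makes no merge. The surviving frequency counts are then converted
#' to probabilities with [to_stochastic()]. Training uses positive windows
#' only; the learned automaton generalizes beyond the training set whenever
#' merging creates loops.
#'
#' The result is deterministic for a fixed input order, `alpha` and alphabet.
#'
#' @param x Training windows: character vector or windows data frame.
#' @param alpha Confidence parameter in (0, 1]; default 0.7. Smaller values
#'   merge more aggressively (see [alergia_different()]).
#' @param smoothing Scoring-time probability floor (default 0.01); `NULL`
#'   disables smoothing.
#' @param min_count States with fewer than `min_count` arriving strings are
#'   never chosen as merge candidates (0, the default, disables the guard).
#' @param alphabet Symbol set.
#' @return A `dsfa` with metadata (`alpha`, `smoothing`, training size).
#' @export
#' @examples
#' dsfa <- infer_dsfa(c("RRKSACP", "RRKSIPK", "RRPSCAL", "RRTSCLI", "RPKSPSK"),
#'   alpha = 0.7
#' )
#' sequence_probability(dsfa, "RRKSACP")
infer_dsfa <- function(x, alpha = 0.7, smoothing = 0.01, min_count = 0,
                       alphabet = aa_alphabet()) {
  sequences <- window_strings(x)
  fa <- build_pta(sequences, alphabet = alphabet)
  fa <- alergia_merge_loop(fa, alpha = alpha, min_count = min_count)
  dsfa <- to_stochastic(fa, smoothing = smoothing)
  dsfa$meta <- list(
    alpha = alpha,
    smoothing = if (is.null(smoothing)) NA_real_ else smoothing,
    min_count = min_count,
    n_training = length(sequences)
  )
  dsfa
}

# the quadratic pair scan: j ascending over surviving states, i ascending
# below j; first compatible pair is folded and the scan moves to the next j;
# passes repeat until a full pass makes no merge
alergia_merge_loop <- function(fa, alpha, min_count = 0) {
  repeat {
    merged_any <- FALSE
    j <- 2L
    while (j <= length(fa$n)) {
      if (fa$alive[j] && fa$n[j] >= min_count) {
        for (i in seq_len(j - 1L)) {
          if (!fa$alive[i] || fa$n[i] < min_count) next
          if (alergia_compatible(fa, i, j, alpha)) {
            fa <- quotient_merge(fa, list(c(i, j)))
            merged_any <- TRUE
            break
          }
        }
      }
      j <- j + 1L
    }
    if (!merged_any) break
  }
  fa
}
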