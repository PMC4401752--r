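#' Generation probability of a window under a stochastic automaton
#'
#' For a deterministic automaton the probability of a string is the product of
#' the transition probabilities along its unique state path, times the final
#' probability at the terminal state. With smoothing enabled (the default when
#' the model carries a smoothing value), every zero or missing probability
#' consulted along the way contributes the smoothing floor instead, so unseen
#' windows always score above zero; once the path leaves the automaton, each
#' remaining step contributes the floor.
#'
#' @param dsfa A `dsfa` object.
#' @param w Character vector of windows to score.
#' @param smoothed Use the model's smoothing floor (default `TRUE`; ignored if
#'   the model was built without smoothing).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
#' @examples
#' m <- to_stochastic(build_pta(c("AB", "AB", "AA"), alphabet = c("A", "B")), smoothing = NULL)
#' sequence_probability(m, c("AB", "AA", "BB"))
sequence_probability <- function(dsfa, w, smoothed = TRUE) {
  stopifnot(inherits(dsfa, "dsfa"))
  s <- if (smoothed && !is.na(dsfa$smoothing)) dsfa$smoothing else 0
  syms_list <- split_symbols(w, dsfa$alphabet)
  vapply(syms_list, function(syms) {
    cur <- dsfa$initial
    p <- 1
    alive <- TRUE
    for (a in syms) {
      if (alive) {
        nxt <- dsfa$trans[[cur]][a]
        if (!is.na(nxt)) {
          p <- p * dsfa$probs[[cur]][[a]]
          cur <- nxt[[1]]
          next
        }
        alive <- FALSE
      }
      p <- p * s
    }
    pe <- if (alive) dsfa$p_end[cur] else 0
    p * (if (pe > 0) pe else s)
  }, numeric(1))
}

#' Classify candidate windows against a probability threshold
#'
#' A window is called a phosphosite when its generation probability is at
#' least `threshold`. The conventional operating point for 7-residue windows
#' is 0.008.
#'
#' @param windows Windows data frame (column `window`) or character vector.
#' @param dsfa A `dsfa` model.
#' @param threshold Decision threshold in `[0, 1]` (default 0.008).
#' @param smoothed Score with the model's smoothing floor (default `TRUE`).
#' @return A tibble: the input windows plus `probability` and `call` columns.
#' @export
classify_windows <- function(windows, dsfa, threshold = 0.008, smoothed = TRUE) {
  if (threshold < 0 || threshold > 1) {
    abort("threshold must be in [0, 1]", class = "phosgram_config_error")
  }
  strings <- window_strings(windows, "windows")
  out <- if (is.data.frame(windows)) as_tibble(windows) else tibble(window = strings)
  out$probability <- sequence_probability(dsfa, strings, smoothed = smoothed)
  out$call <- out$probability >= threshold
  out
}

#' Localize the phosphorylated residue within a window
#'
#' Walks the window's unique state path through the automaton and records, at
#' every S/T occurrence, the emission probability of that symbol from the
#' current state (the smoothing floor where the step is missing). The S/T with
#' the highest emission probability is reported as the putative
#' phosphorylated residue; ties go to the leftmost. Offsets are relative to
#' the window center (center = 0, negative = upstream).
#'
#' @param dsfa A `dsfa` model.
#' @param window A single window string containing at least one S or T.
#' @param smoothed Use the smoothing floor for missing steps (default `TRUE`).
#' @return A one-row tibble with `offset`, `position` (1-based within the
#'   window), `residue` and `emission_probability`.
#' @export
localize_site <- function(dsfa, window, smoothed = TRUE) {
  stopifnot(inherits(dsfa, "dsfa"), length(window) == 1)
  syms <- split_symbols(window, dsfa$alphabet)[[1]]
  cand <- which(syms %in% c("S", "T"))
  if (length(cand) == 0) {
    abort("window contains no S or T residue", class = "phosgram_no_candidate_error")
  }
  s <- if (smoothed && !is.na(dsfa$smoothing)) dsfa$smoothing else 0
  emis <- rep(NA_real_, length(syms))
  cur <- dsfa$initial
  alive <- TRUE
  for (k in seq_along(syms)) {
    a <- syms[k]
    if (alive && !is.na(dsfa$trans[[cur]][a])) {
      emis[k] <- dsfa$probs[[cur]][[a]]
      cur <- dsfa$trans[[cur]][a][[1]]
    } else {
      alive <- FALSE
      emis[k] <- s
    }
  }
  best <- cand[which.max(emis[cand])] # which.max breaks ties leftmost
  center <- (length(syms) + 1L) %/% 2L
  tibble(
    offset = best - center,
    position = best,
    residue = syms[best],
    emission_probability = emis[best]
  )
}

#' Scan a protein for candidate phosphosites
#'
#' Extracts a window at every S/T position of the protein (X-padded at the
#' termini), scores each under the model and classifies it against the
#' threshold.
#'
#' @param dsfa A `dsfa` model.
#' @param protein Amino-acid string (single protein).
#' @param threshold Decision threshold (default 0.008).
#' @param flank Residues on each side of the candidate site; window width is
#'   `2 * flank + 1`. Must match the flank the model was trained at.
#' @param protein_id Identifier recorded in the output.
#' @return A tibble sorted by `site_position` with `window`, `probability` and
#'   `call` columns; empty (zero rows) when the protein has no S/T.
#' @export
scan_protein <- function(dsfa, protein, threshold = 0.008, flank = 3,
                         protein_id = "protein") {
  stopifnot(length(protein) == 1, nchar(protein) > 0)
  syms <- strsplit(protein, "", fixed = TRUE)[[1]]
  sites <- which(syms %in% c("S", "T"))
  if (length(sites) == 0) {
    return(tibble(
      protein_id = character(0), site_position = integer(0),
      window = character(0), probability = numeric(0), call = logical(0)
    ))
  }
  wins <- extract_window(protein, sites, flank = flank, protein_id = protein_id)
  out <- classify_windows(wins, dsfa, threshold = threshold)
  dplyr::arrange(
    dplyr::select(out, "protein_id", "site_position", "window", "probability", "call"),
    .data$site_position
  )
}

#' @export
predict.dsfa <- function(object, newdata, threshold = 0.008, smoothed = TRUE, ...) {
  classify_windows(newdata, object, threshold = threshold, smoothed = smoothed)
}
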