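#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Named character vector (names are the FASTA record ids, first
#'   whitespace-delimited token).
#' @export
read_fasta_proteins <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required to read FASTA files", class = "phosgram_io_error")
  }
  seqs <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  out
}

#' Read a phosphosite annotation table
#'
#' Tab-separated columns `protein_id`, `position` (1-based) and optionally
#' `kinase`.
#'
#' @param path TSV file.
#' @return A tibble.
#' @export
read_site_annotations <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("protein_id", "position") %in% names(out))) {
    abort("annotation TSV needs columns protein_id, position",
      class = "phosgram_io_error"
    )
  }
  out$position <- as.integer(out$position)
  out
}

#' Read and write window tables
#'
#' Tab-separated columns `protein_id`, `site_position`, `window`, `label`,
#' `kinase`.
#'
#' @param path TSV file.
#' @param windows A windows tibble.
#' @return `read_windows()` a tibble; `write_windows()` the input, invisibly.
#' @export
read_windows <- function(path) {
  out <- readr::read_tsv(path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      site_position = readr::col_integer(),
      window = readr::col_character(),
      label = readr::col_character(),
      kinase = readr::col_character()
    )
  )
  if (!"window" %in% names(out)) {
    abort("window TSV needs a `window` column", class = "phosgram_io_error")
  }
  out
}

#' @rdname read_windows
#' @export
write_windows <- function(windows, path) {
  readr::write_tsv(as_tibble(windows), path)
  invisible(windows)
}

#' Serialize a stochastic automaton to JSON
#'
#' The document carries the alphabet, initial state, per-state counts and
#' final probabilities, the transition list (from, symbol, to, count,
#' probability) and free-form metadata (alpha, smoothing, flank, threshold,
#' training size, ...). [read_dsfa()] restores an identical model.
#'
#' @param dsfa A `dsfa` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dsfa <- function(dsfa, path) {
  stopifnot(inherits(dsfa, "dsfa"))
  n_st <- length(dsfa$p_end)
  trans <- purrr::map_dfr(seq_len(n_st), function(i) {
    tr <- dsfa$trans[[i]]
    if (length(tr) == 0) {
      return(tibble(
        from = integer(0), symbol = character(0), to = integer(0),
        count = integer(0), prob = numeric(0)
      ))
    }
    tibble(
      from = i, symbol = names(tr), to = unname(tr),
      count = unname(dsfa$counts[[i]][names(tr)]),
      prob = unname(dsfa$probs[[i]][names(tr)])
    )
  })
  doc <- list(
    format = "phosgram-dsfa",
    alphabet = dsfa$alphabet,
    initial_state = dsfa$initial,
    states = list(
      id = seq_len(n_st), n = dsfa$n, f_end = dsfa$f_end
    ),
    transitions = trans,
    final_probs = dsfa$p_end,
    smoothing = dsfa$smoothing,
    metadata = dsfa$meta
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Restore a stochastic automaton from JSON
#'
#' @param path File written by [write_dsfa()].
#' @return A `dsfa` object.
#' @export
read_dsfa <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "phosgram-dsfa") {
    abort("not a phosgram DSFA model file", class = "phosgram_io_error")
  }
  n_st <- length(doc$final_probs)
  trans <- vector("list", n_st)
  counts <- vector("list", n_st)
  probs <- vector("list", n_st)
  for (i in seq_len(n_st)) {
    trans[[i]] <- integer(0)
    counts[[i]] <- integer(0)
    probs[[i]] <- numeric(0)
  }
  tr <- doc$transitions
  if (NROW(tr) > 0) {
    for (r in seq_len(nrow(tr))) {
      i <- tr$from[r]
      a <- tr$symbol[r]
      trans[[i]][a] <- as.integer(tr$to[r])
      counts[[i]][a] <- as.integer(tr$count[r])
      probs[[i]][a] <- tr$prob[r]
    }
  }
  structure(
    list(
      alphabet = doc$alphabet, initial = as.integer(doc$initial_state),
      trans = trans, probs = probs,
      p_end = doc$final_probs,
      n = as.integer(doc$states$n), f_end = as.integer(doc$states$f_end),
      counts = counts,
      smoothing = if (is.null(doc$smoothing)) NA_real_ else doc$smoothing,
      meta = doc$metadata
    ),
    class = "dsfa"
  )
}

#' Export an automaton in Graphviz DOT format
#'
#' States are nodes (double circles for accepting / high-termination states);
#' edges are labelled `symbol:probability` for stochastic automata and
#' `symbol` otherwise.
#'
#' @param x A `dsfa`, `dfa` or `freq_automaton`.
#' @param path Optional output file; when `NULL` the DOT text is returned.
#' @return The DOT document as a character scalar (invisibly when written).
#' @export
automaton_dot <- function(x, path = NULL) {
  lines <- c("digraph automaton {", "  rankdir=LR;", "  node [shape=circle];")
  if (inherits(x, "freq_automaton")) {
    ids <- which(x$alive)
    for (i in ids) {
      shape <- if (x$f_end[i] > 0) "doublecircle" else "circle"
      lines <- c(lines, sprintf("  q%d [shape=%s, label=\"q%d\\nn=%d\"];", i, shape, i, x$n[i]))
      tr <- x$trans[[i]]
      for (a in names(tr)) {
        lines <- c(lines, sprintf(
          "  q%d -> q%d [label=\"%s:%d\"];", i, tr[[a]], a, x$counts[[i]][[a]]
        ))
      }
    }
  } else if (inherits(x, "dsfa")) {
    for (i in seq_along(x$p_end)) {
      shape <- if (x$p_end[i] > 0) "doublecircle" else "circle"
      lines <- c(lines, sprintf(
        "  q%d [shape=%s, label=\"q%d\\nend=%.3g\"];", i, shape, i, x$p_end[i]
      ))
      tr <- x$trans[[i]]
      for (a in names(tr)) {
        lines <- c(lines, sprintf(
          "  q%d -> q%d [label=\"%s:%.3g\"];", i, tr[[a]], a, x$probs[[i]][[a]]
        ))
      }
    }
  } else if (inherits(x, "dfa")) {
    for (i in seq_along(x$accepting)) {
      shape <- if (x$accepting[i]) "doublecircle" else "circle"
      lines <- c(lines, sprintf("  q%d [shape=%s];", i, shape))
      tr <- x$trans[[i]]
      for (a in names(tr)) {
        lines <- c(lines, sprintf("  q%d -> q%d [label=\"%s\"];", i, tr[[a]], a))
      }
    }
  } else {
    abort("unsupported automaton type", class = "phosgram_type_error")
  }
  dot <- paste(c(lines, "}"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
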