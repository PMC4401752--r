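#' Extract fixed-width windows around candidate phosphosites
#'
#' Returns the `2 * flank + 1` residues centered on each requested site,
#' padding positions that fall outside the protein with `X` (the "any
#' residue" symbol) so the phosphorylated residue always sits at the window
#' center. Positions are 1-based and inclusive; every requested site must be
#' an S or T.
#'
#' @param protein Amino-acid string (single protein).
#' @param sites Integer vector of 1-based residue positions.
#' @param flank Non-negative number of residues kept on each side.
#' @param protein_id Identifier recorded in the output.
#' @param label Window label: `"positive"`, `"negative"` or `"unknown"`.
#' @param kinase Optional kinase tag.
#' @return A tibble with columns `protein_id`, `site_position`, `window`,
#'   `label`, `kinase` (one row per site).
#' @export
#' @examples
#' extract_window("MKRRKSACPL", 6, flank = 3)$window # "RRKSACP"
extract_window <- function(protein, sites, flank = 3, protein_id = "protein",
                           label = "unknown", kinase = NA_character_) {
  stopifnot(length(protein) == 1, flank >= 0)
  syms <- strsplit(protein, "", fixed = TRUE)[[1]]
  len <- length(syms)
  sites <- as.integer(sites)
  if (any(sites < 1 | sites > len)) {
    abort("site position outside the protein", class = "phosgram_range_error")
  }
  centers <- syms[sites]
  if (!all(centers %in% c("S", "T"))) {
    bad <- sites[!centers %in% c("S", "T")]
    abort(
      sprintf("center residue is not S/T at position(s) %s", paste(bad, collapse = ", ")),
      class = "phosgram_invalid_site_error"
    )
  }
  windows <- vapply(sites, function(s) {
    idx <- (s - flank):(s + flank)
    chars <- ifelse(idx < 1 | idx > len, "X", syms[pmax(pmin(idx, len), 1)])
    paste(chars, collapse = "")
  }, character(1))
  tibble(
    protein_id = protein_id, site_position = sites,
    window = windows, label = label, kinase = kinase
  )
}

#' Trim stored windows to a narrower flank
#'
#' Keeps the central `2 * flank + 1` residues of each window, e.g. to derive
#' 7-mers from stored 21-mers. The canonical path is to re-extract windows at
#' the desired flank; this utility serves stored window tables.
#'
#' @param windows Windows data frame or character vector (odd, equal lengths).
#' @param flank Target flank, at most the stored flank.
#' @return Same shape as the input with trimmed `window` strings.
#' @export
trim_window <- function(windows, flank) {
  strings <- window_strings(windows, "windows")
  width <- unique(nchar(strings))
  if (length(width) != 1 || width %% 2 == 0) {
    abort("windows must share a single odd width", class = "phosgram_shape_error")
  }
  if (2 * flank + 1 > width) {
    abort("target flank exceeds the stored flank", class = "phosgram_config_error")
  }
  center <- (width + 1) %/% 2
  trimmed <- substr(strings, center - flank, center + flank)
  if (is.data.frame(windows)) {
    out <- as_tibble(windows)
    out$window <- trimmed
    out
  } else {
    trimmed
  }
}

#' Remove redundant windows by greedy identity filtering
#'
#' Greedy single-pass clustering in input order: a window is kept when its
#' ungapped column-wise identity to every previously kept window is at most
#' `identity_threshold`. Windows are equal-length, so ungapped column identity
#' (fraction of matching positions) stands in for an alignment-based
#' redundancy filter. Deterministic for a given input order, and idempotent.
#'
#' @param windows Windows data frame or character vector (equal lengths).
#' @param identity_threshold Maximum allowed pairwise identity in (0, 1];
#'   default 0.6 (windows more than 60% identical to a kept one are dropped).
#' @return The kept subset, same shape as the input.
#' @export
#' @examples
#' filter_redundant(c("RRKSACP", "RRKSACL", "GGGSGGG"), identity_threshold = 0.6)
filter_redundant <- function(windows, identity_threshold = 0.6) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    abort("identity_threshold must be in (0, 1]", class = "phosgram_config_error")
  }
  strings <- window_strings(windows, "windows")
  if (length(strings) == 0) return(windows)
  widths <- nchar(strings)
  if (length(unique(widths)) != 1) {
    abort("windows must all have the same length", class = "phosgram_shape_error")
  }
  mat <- do.call(rbind, strsplit(strings, "", fixed = TRUE))
  width <- ncol(mat)
  kept <- integer(0)
  for (i in seq_along(strings)) {
    redundant <- FALSE
    for (k in kept) {
      if (mean(mat[i, ] == mat[k, ]) > identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  if (is.data.frame(windows)) as_tibble(windows)[kept, ] else strings[kept]
}

#' Split windows into a training set and a class-balanced test set
#'
#' Positives are shuffled with the given seed; the first
#' `floor(train_fraction * n)` go to training (the automaton trains on
#' positives only) and the rest to the test set. Test negatives are sampled
#' without replacement (same seed) so that the test set keeps exactly
#' `neg_ratio` negatives per positive. Reproducible for a fixed seed.
#'
#' @param positives,negatives Windows data frames (or character vectors).
#' @param train_fraction Fraction of positives used for training, in (0, 1);
#'   default 0.6.
#' @param neg_ratio Test negatives per test positive (default 10).
#' @param seed Integer seed.
#' @return An object of class `phosgram_split`: a list with tibbles
#'   `train_positives`, `test_positives`, `test_negatives` and the split
#'   parameters.
#' @export
assemble_split <- function(positives, negatives, train_fraction = 0.6,
                           neg_ratio = 10, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)", class = "phosgram_config_error")
  }
  pos <- as_windows_tibble(positives, "positive")
  neg <- as_windows_tibble(negatives, "negative")
  n <- nrow(pos)
  if (n == 0) abort("no positive windows", class = "phosgram_empty_input_error")
  n_train <- floor(train_fraction * n)
  n_test <- n - n_train
  n_neg <- neg_ratio * n_test
  if (nrow(neg) < n_neg) {
    abort(
      sprintf(
        "need %d test negatives for a 1:%d ratio but only %d available",
        n_neg, neg_ratio, nrow(neg)
      ),
      class = "phosgram_ratio_error"
    )
  }
  with_seed_(seed, {
    perm <- sample.int(n)
    neg_idx <- sample.int(nrow(neg), n_neg)
    structure(
      list(
        train_positives = pos[perm[seq_len(n_train)], ],
        test_positives = pos[perm[setdiff(seq_len(n), seq_len(n_train))], ],
        test_negatives = neg[neg_idx, ],
        train_fraction = train_fraction, neg_ratio = neg_ratio, seed = seed
      ),
      class = "phosgram_split"
    )
  })
}

#' @export
print.phosgram_split <- function(x, ...) {
  cat(sprintf(
    "<phosgram_split: %d train positives, %d test positives, %d test negatives (1:%d)>\n",
    nrow(x$train_positives), nrow(x$test_positives), nrow(x$test_negatives),
    x$neg_ratio
  ))
  invisible(x)
}

# coerce character vectors to a minimal windows tibble
as_windows_tibble <- function(x, label) {
  if (is.character(x)) {
    return(tibble(
      protein_id = NA_character_,
      site_position = NA_integer_,
      window = x, label = label, kinase = NA_character_
    ))
  }
  as_tibble(x)
}

#' Build positive and negative window sets from proteins and site annotations
#'
#' Positives are windows centered on annotated phosphosites; negatives are
#' windows centered on every other S/T of the same substrate proteins.
#' Duplicate (protein, position) annotations collapse to one window (first
#' occurrence wins).
#'
#' @param proteins Named character vector of protein sequences (names are
#'   protein ids), e.g. from [read_fasta_proteins()].
#' @param annotations Data frame with columns `protein_id`, `position`
#'   (1-based) and optionally `kinase`.
#' @param flank Window flank (default 3).
#' @return A tibble of windows labelled `"positive"` / `"negative"`.
#' @export
windows_from_proteins <- function(proteins, annotations, flank = 3) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  annotations <- as_tibble(annotations)
  if (!all(c("protein_id", "position") %in% names(annotations))) {
    abort("annotations need `protein_id` and `position` columns",
      class = "phosgram_type_error"
    )
  }
  if (!"kinase" %in% names(annotations)) annotations$kinase <- NA_character_
  annotations <- dplyr::distinct(annotations, .data$protein_id, .data$position,
    .keep_all = TRUE
  )
  missing <- setdiff(unique(annotations$protein_id), names(proteins))
  if (length(missing) > 0) {
    abort(
      sprintf("annotated proteins not in FASTA: %s", paste(missing, collapse = ", ")),
      class = "phosgram_range_error"
    )
  }
  purrr::map_dfr(names(proteins), function(id) {
    seq <- proteins[[id]]
    ann <- annotations[annotations$protein_id == id, ]
    syms <- strsplit(seq, "", fixed = TRUE)[[1]]
    st <- which(syms %in% c("S", "T"))
    pos_sites <- ann$position
    rows <- list()
    if (length(pos_sites) > 0) {
      rows$pos <- extract_window(seq, pos_sites,
        flank = flank, protein_id = id,
        label = "positive"
      )
      rows$pos$kinase <- ann$kinase
    }
    neg_sites <- setdiff(st, pos_sites)
    if (length(neg_sites) > 0) {
      rows$neg <- extract_window(seq, neg_sites,
        flank = flank, protein_id = id,
        label = "negative"
      )
    }
    dplyr::bind_rows(rows)
  })
}
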