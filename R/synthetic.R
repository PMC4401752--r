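#' Uniform amino-acid background composition
#'
#' @return Named numeric vector over the 20 standard amino acids summing to 1.
#' @export
uniform_background <- function() {
  aa <- aa_alphabet(include_x = FALSE)
  setNames(rep(1 / length(aa), length(aa)), aa)
}

#' Specify a synthetic kinase substrate motif
#'
#' Describes windows of width `2 * flank + 1` centered on an S/T, with
#' positional preferences at offsets relative to the center (offset 0 is the
#' site itself and is excluded). Each preferred offset draws a residue from
#' its residue set with probability `adherence`, otherwise from the
#' background; all other offsets draw from the background. This emulates the
#' consensus-motif structure of kinase substrate sites (e.g. basic residues
#' just upstream of PKA sites) without claiming any particular biology.
#'
#' @param flank Window flank (default 3, i.e. 7-mers).
#' @param center_residues Residues allowed at the center (subset of S/T).
#' @param preferences Named list: names are signed offsets (e.g. `"-3"`),
#'   values are lists with `residues` (character vector) and `adherence`
#'   (probability).
#' @param background Named frequency table over the 20 amino acids summing
#'   to 1.
#' @param name Label recorded in generated windows.
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(flank = 3, center_residues = c("S", "T"),
                       preferences = list(), background = uniform_background(),
                       name = "synthetic") {
  if (length(center_residues) == 0 || !all(center_residues %in% c("S", "T"))) {
    abort("center_residues must be a nonempty subset of S/T",
      class = "phosgram_spec_error"
    )
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    abort("background frequencies must be non-negative and sum to 1",
      class = "phosgram_spec_error"
    )
  }
  offs <- as.integer(names(preferences))
  if (length(preferences) > 0) {
    if (any(is.na(offs)) || any(offs == 0) || any(abs(offs) > flank)) {
      abort("preference offsets must be nonzero integers within the flank",
        class = "phosgram_spec_error"
      )
    }
    for (p in preferences) {
      if (p$adherence < 0 || p$adherence > 1) {
        abort("adherence must be in [0, 1]", class = "phosgram_spec_error")
      }
    }
  }
  structure(
    list(
      flank = flank, center_residues = center_residues,
      preferences = preferences, background = background, name = name
    ),
    class = "motif_spec"
  )
}

#' Named kinase-style motif presets
#'
#' Four presets loosely styled after well-known serine/threonine kinase
#' substrate preferences, intended as test fixtures rather than biological
#' claims: `"PKA"` (basic R/K/H at -3 and -2), `"CK2"` (acidic D/E at +1 and
#' +3), `"MAPK"` (proline at +1) and `"PKC"` (basic at -3 and +2).
#'
#' @param name One of `"PKA"`, `"CK2"`, `"MAPK"`, `"PKC"`.
#' @param flank Window flank (default 3).
#' @param adherence Probability that a preferred offset respects the motif
#'   (default 0.95).
#' @return A [motif_spec()].
#' @export
#' @examples
#' motif_preset("PKA")
motif_preset <- function(name = c("PKA", "CK2", "MAPK", "PKC"), flank = 3,
                         adherence = 0.95) {
  name <- match.arg(name)
  basic <- c("R", "K", "H")
  acidic <- c("D", "E")
  prefs <- switch(name,
    PKA = list(`-3` = basic, `-2` = basic),
    CK2 = list(`+1` = acidic, `+3` = acidic),
    MAPK = list(`+1` = "P"),
    PKC = list(`-3` = basic, `+2` = basic)
  )
  prefs <- lapply(prefs, function(res) list(residues = res, adherence = adherence))
  names(prefs) <- as.character(as.integer(names(prefs)))
  motif_spec(flank = flank, preferences = prefs, name = name)
}

#' Generate positive (motif-bearing) substrate windows
#'
#' @param spec A [motif_spec()].
#' @param n Number of windows (>= 1).
#' @param seed Integer seed; the output is reproducible per seed.
#' @return A windows tibble labelled `"positive"`.
#' @export
generate_positives <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "motif_spec"), n >= 1)
  aa <- names(spec$background)
  width <- 2L * spec$flank + 1L
  center <- spec$flank + 1L
  with_seed_(seed, {
    windows <- vapply(seq_len(n), function(i) {
      w <- sample(aa, width, replace = TRUE, prob = spec$background)
      w[center] <- if (length(spec$center_residues) == 1) {
        spec$center_residues
      } else {
        sample(spec$center_residues, 1)
      }
      for (off_chr in names(spec$preferences)) {
        pref <- spec$preferences[[off_chr]]
        if (stats::runif(1) < pref$adherence) {
          pos <- center + as.integer(off_chr)
          w[pos] <- if (length(pref$residues) == 1) {
            pref$residues
          } else {
            sample(pref$residues, 1)
          }
        }
      }
      paste(w, collapse = "")
    }, character(1))
    tibble(
      protein_id = sprintf("%s_pos_%05d", spec$name, seq_len(n)),
      site_position = center,
      window = windows, label = "positive", kinase = spec$name
    )
  })
}

#' Generate negative (motif-free) S/T-centered windows
#'
#' Windows whose center is S or T but whose remaining positions are drawn
#' purely from the background composition, emulating non-phosphorylated S/T
#' residues.
#'
#' @param background Named frequency table over the 20 amino acids.
#' @param flank Window flank (default 3).
#' @param n Number of windows (>= 1).
#' @param seed Integer seed.
#' @return A windows tibble labelled `"negative"`.
#' @export
generate_negatives <- function(background = uniform_background(), flank = 3,
                               n = 1, seed = NULL) {
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    abort("background frequencies must be non-negative and sum to 1",
      class = "phosgram_spec_error"
    )
  }
  stopifnot(n >= 1)
  aa <- names(background)
  width <- 2L * flank + 1L
  center <- flank + 1L
  with_seed_(seed, {
    windows <- vapply(seq_len(n), function(i) {
      w <- sample(aa, width, replace = TRUE, prob = background)
      w[center] <- sample(c("S", "T"), 1)
      paste(w, collapse = "")
    }, character(1))
    tibble(
      protein_id = sprintf("background_neg_%05d", seq_len(n)),
      site_position = center,
      window = windows, label = "negative", kinase = NA_character_
    )
  })
}
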