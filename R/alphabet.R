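#' The amino-acid alphabet used for substrate windows
#'
#' The 20 standard amino acids plus `X`, the padding symbol used when a window
#' extends past a protein terminus (`X` stands for "any residue"). All automata
#' default to this alphabet; toy alphabets (e.g. `c("A", "B")`) are accepted
#' everywhere an `alphabet` argument appears.
#'
#' @param include_x Include the `X` padding symbol (default `TRUE`).
#' @return Character vector of single-letter symbols.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function(include_x = TRUE) {
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  if (include_x) c(aa, "X") else aa
}

# split a vector of strings into a list of character vectors, validating symbols
split_symbols <- function(strings, alphabet) {
  syms <- strsplit(strings, "", fixed = TRUE)
  bad <- setdiff(unique(unlist(syms)), alphabet)
  if (length(bad) > 0) {
    abort(
      sprintf("symbols outside the alphabet: %s", paste(bad, collapse = ", ")),
      class = "phosgram_alphabet_error"
    )
  }
  syms
}

# accept either a windows tibble (column `window`) or a character vector
window_strings <- function(x, arg = "x") {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    if (!"window" %in% names(x)) {
      abort(sprintf("`%s` must have a `window` column", arg),
        class = "phosgram_type_error"
      )
    }
    return(x$window)
  }
  abort(sprintf("`%s` must be a character vector or a windows data frame", arg),
    class = "phosgram_type_error"
  )
}
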