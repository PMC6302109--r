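#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn %||%
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap list_rbind
#' @importFrom stringr str_split str_detect str_locate_all str_sub str_to_upper
NULL

AA_LETTERS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
NT_LETTERS <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split a sequence string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

assert_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    abort(sprintf("`%s` must be a single non-empty string.", name))
  }
}

# Validate a sequence against an alphabet; `extra` letters (N/X) are tolerated.
# Reports the 1-based position of the first offending character.
check_alphabet <- function(sequence, id, letters, extra) {
  chars <- seq_chars(sequence)
  bad <- which(!(chars %in% c(letters, extra)))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Record '%s': character '%s' at position %d is outside the allowed alphabet.",
      id, chars[bad[1L]], bad[1L]
    ))
  }
  invisible(TRUE)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
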