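#' Reference anchors
#'
#' A reference anchor is a peptide used to impose its residue numbering onto
#' query peptides via pairwise alignment, together with named single positions
#' (e.g. `pos762`) and named windows (1-based inclusive spans). All analysis
#' windows in this package are expressed in reference coordinates:
#'
#' * PolA anchor: `partial` = 675..799 (125 aa), `full_domain` = 547..926
#'   (380 aa), `concat` = 784..926 (143 aa); named position `pos762` = 762.
#' * RNR (NrdA) anchor: `rnr_region` = 437..625 (189 aa).
#'
#' @param name Anchor name.
#' @param peptide Anchor peptide sequence (20-letter alphabet).
#' @param positions Named integer vector of labelled reference positions.
#' @param windows Named list of `c(start, end)` integer pairs.
#' @return An object of class `reference_anchor`.
#' @export
reference_anchor <- function(name, peptide, positions = integer(), windows = list()) {
  assert_scalar_string(name, "name")
  assert_scalar_string(peptide, "peptide")
  check_alphabet(peptide, name, AA_LETTERS, "X")
  L <- nchar(peptide)
  for (lab in names(positions)) {
    p <- positions[[lab]]
    if (p < 1 || p > L) abort(sprintf("Position '%s' (%d) outside anchor '%s' [1, %d].", lab, p, name, L))
  }
  for (lab in names(windows)) {
    w <- windows[[lab]]
    if (length(w) != 2L || w[1] > w[2] || w[1] < 1 || w[2] > L) {
      abort(sprintf("Window '%s' invalid for anchor '%s' (length %d).", lab, name, L))
    }
  }
  structure(
    list(
      name = name, peptide = peptide,
      positions = vapply(positions, as.integer, 1L),
      windows = lapply(windows, as.integer)
    ),
    class = "reference_anchor"
  )
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat(sprintf(
    "<reference_anchor> %s (%d aa); positions: %s; windows: %s\n",
    x$name, nchar(x$peptide),
    paste(names(x$positions), collapse = ", "),
    paste(sprintf("%s[%d-%d]", names(x$windows),
      vapply(x$windows, `[`, 1L, 1),
      vapply(x$windows, `[`, 1L, 2)
    ), collapse = ", ")
  ))
  invisible(x)
}

#' Length of a named anchor window
#' @param anchor A [reference_anchor()].
#' @param label Window label.
#' @return Integer window length (positions, inclusive).
#' @export
window_length <- function(anchor, label) {
  w <- anchor$windows[[label]]
  if (is.null(w)) abort(sprintf("Anchor '%s' has no window '%s'.", anchor$name, label))
  w[2] - w[1] + 1L
}

# Deterministic random peptide; first residue forced to M so scaffolds are
# directly reverse-translatable into ATG-initiated ORFs.
random_peptide <- function(n, seed) {
  with_seed(seed, {
    chars <- sample(AA_LETTERS, n, replace = TRUE)
    chars[1] <- "M"
    paste(chars, collapse = "")
  })
}

#' Synthetic anchor panel
#'
#' Returns the bundled anchor panel: deterministically generated *synthetic*
#' stand-ins with the geometry of the E. coli reference proteins used for
#' residue numbering -- a 928-aa PolA-like scaffold carrying phenylalanine at
#' position 762, and a 761-aa NrdA-like (class I RNR alpha subunit) scaffold.
#' They carry the standard analysis windows (see [reference_anchor()]).
#' A user-supplied real anchor panel can be loaded with [read_anchor_panel()].
#'
#' @return A named list with elements `pola` and `nrda`, each a
#'   [reference_anchor()].
#' @export
anchor_panel <- function() {
  pola_seq <- random_peptide(928, seed = 762001)
  pola_chars <- seq_chars(pola_seq)
  pola_chars[762] <- "F"
  pola_seq <- paste(pola_chars, collapse = "")
  nrda_seq <- random_peptide(761, seed = 437001)
  list(
    pola = reference_anchor(
      "synthetic_pola_anchor", pola_seq,
      positions = c(pos762 = 762L),
      windows = list(
        partial = c(675L, 799L),
        full_domain = c(547L, 926L),
        concat = c(784L, 926L)
      )
    ),
    nrda = reference_anchor(
      "synthetic_nrda_anchor", nrda_seq,
      windows = list(rnr_region = c(437L, 625L))
    )
  )
}

#' Write / read an anchor panel
#'
#' The on-disk form is a peptide FASTA plus a sidecar TSV with columns
#' `anchor_name`, `label`, `start`, `end` (single positions have
#' `start == end` and a label beginning with `pos`).
#'
#' @param panel A named list of [reference_anchor()] objects.
#' @param fasta,tsv Output/input paths.
#' @return `write_anchor_panel()` returns the paths invisibly;
#'   `read_anchor_panel()` returns a named list of anchors keyed by the list
#'   names used at write time (lower-cased anchor names).
#' @export
write_anchor_panel <- function(panel, fasta, tsv) {
  recs <- tibble(
    id = vapply(panel, function(a) a$name, ""),
    sequence = vapply(panel, function(a) a$peptide, "")
  )
  write_fasta(recs, fasta)
  rows <- purrr::imap(panel, function(a, key) {
    bind_rows(
      tibble(
        anchor_name = a$name, label = names(a$positions),
        start = unname(a$positions), end = unname(a$positions)
      ),
      tibble(
        anchor_name = a$name, label = names(a$windows),
        start = vapply(a$windows, `[`, 1L, 1),
        end = vapply(a$windows, `[`, 1L, 2)
      )
    )
  }) |> list_rbind()
  write_tsv_table(rows, tsv)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname write_anchor_panel
#' @export
read_anchor_panel <- function(fasta, tsv) {
  recs <- read_fasta(fasta, "amino-acid")
  side <- read_tsv_table(tsv)
  out <- list()
  for (i in seq_len(nrow(recs))) {
    nm <- recs$id[i]
    s <- side[side$anchor_name == nm, , drop = FALSE]
    pos_rows <- s[s$start == s$end & grepl("^pos", s$label), , drop = FALSE]
    win_rows <- s[!(s$label %in% pos_rows$label), , drop = FALSE]
    positions <- stats::setNames(as.integer(pos_rows$start), pos_rows$label)
    windows <- stats::setNames(
      purrr::map2(win_rows$start, win_rows$end, function(a, b) c(as.integer(a), as.integer(b))),
      win_rows$label
    )
    out[[tolower(nm)]] <- reference_anchor(nm, recs$sequence[i], positions, windows)
  }
  out
}
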