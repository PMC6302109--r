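#' Alignment scoring parameters
#'
#' Fixed substitution/gap parameters shared by the global anchoring and local
#' screening alignments, plus the Karlin-Altschul constants used to convert
#' local scores into E-value estimates. The constants are the standard gapped
#' BLOSUM62 (gap open 11 / extend 1) values and are pinned here so results are
#' reproducible.
#'
#' @param gap_open,gap_extend Affine gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`).
#' @param lambda,K Karlin-Altschul parameters for `E = K * m * n * exp(-lambda * S)`.
#' @return A list of alignment parameters.
#' @export
align_params <- function(gap_open = 11, gap_extend = 1, lambda = 0.267, K = 0.041) {
  list(
    matrix = "BLOSUM62", gap_open = gap_open, gap_extend = gap_extend,
    lambda = lambda, K = K
  )
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Ends-free global alignment of a query against an anchor
#'
#' Needleman-Wunsch alignment under BLOSUM62 with affine gaps in which
#' terminal gaps on either sequence are free, so a query fragment aligns to
#' the matching anchor region and unrelated query flanks overhang at no cost.
#' The returned aligned strings cover both sequences in full (overhangs are
#' stacked against gaps), so removing `-` from either string recovers the
#' original sequence.
#'
#' @param query,anchor_peptide Peptide sequences (non-empty).
#' @param params [align_params()].
#' @return A list of class `anchored_alignment` with elements `query_aligned`,
#'   `ref_aligned` and `score`.
#' @export
global_align <- function(query, anchor_peptide, params = align_params()) {
  assert_scalar_string(query, "query")
  assert_scalar_string(anchor_peptide, "anchor_peptide")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(anchor_peptide),
    type = "overlap", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  build_overlap_strings(pa, query, anchor_peptide)
}

# Reconstruct full-length aligned strings from a Biostrings overlap alignment:
# unaligned prefixes/suffixes of each sequence are stacked against gap runs
# (query overhang first), keeping every column at least half non-gap.
build_overlap_strings <- function(pa, query, ref) {
  qa_core <- as.character(Biostrings::alignedPattern(pa))
  ra_core <- as.character(Biostrings::alignedSubject(pa))
  qs <- Biostrings::start(Biostrings::pattern(pa))
  qe <- Biostrings::end(Biostrings::pattern(pa))
  rs <- Biostrings::start(Biostrings::subject(pa))
  re <- Biostrings::end(Biostrings::subject(pa))
  q_pre <- substr(query, 1L, qs - 1L)
  q_suf <- substr(query, qe + 1L, nchar(query))
  r_pre <- substr(ref, 1L, rs - 1L)
  r_suf <- substr(ref, re + 1L, nchar(ref))
  gaps <- function(n) strrep("-", n)
  query_aligned <- paste0(q_pre, gaps(nchar(r_pre)), qa_core, q_suf, gaps(nchar(r_suf)))
  ref_aligned <- paste0(gaps(nchar(q_pre)), r_pre, ra_core, gaps(nchar(q_suf)), r_suf)
  structure(
    list(
      query_aligned = query_aligned, ref_aligned = ref_aligned,
      score = Biostrings::score(pa)
    ),
    class = "anchored_alignment"
  )
}

#' Map reference positions onto query positions
#'
#' For each reference residue, finds the query residue aligned in the same
#' column, or `NA` when that column holds a query gap (a deletion in the
#' query relative to the reference).
#'
#' @param alignment An `anchored_alignment` from [global_align()].
#' @return A tibble with columns `ref_pos` and `query_pos` (`NA` = deleted),
#'   with attribute `query_span` = range of reference positions covered by
#'   aligned (non-gap) query residues, or `c(NA, NA)` when none.
#' @export
coordinate_map <- function(alignment) {
  stopifnot(inherits(alignment, "anchored_alignment"))
  q <- seq_chars(alignment$query_aligned)
  r <- seq_chars(alignment$ref_aligned)
  stopifnot(length(q) == length(r))
  r_nongap <- r != "-"
  q_nongap <- q != "-"
  ref_pos <- cumsum(r_nongap)
  query_pos <- cumsum(q_nongap)
  keep <- r_nongap
  qp <- ifelse(q_nongap[keep], query_pos[keep], NA_integer_)
  out <- tibble(ref_pos = ref_pos[keep], query_pos = as.integer(qp))
  mapped <- out$ref_pos[!is.na(out$query_pos)]
  attr(out, "query_span") <- if (length(mapped)) range(mapped) else c(NA_integer_, NA_integer_)
  out
}

# Align each peptide to the anchor once and cache the ref->query map as an
# integer vector (length = anchor length, NA = deleted/unaligned).
anchor_maps <- function(peptides, anchor, params = align_params()) {
  stopifnot(is.data.frame(peptides), all(c("id", "sequence") %in% names(peptides)))
  if (nrow(peptides) == 0L) return(stats::setNames(list(), character()))
  pats <- Biostrings::AAStringSet(peptides$sequence)
  pa <- Biostrings::pairwiseAlignment(
    pats, Biostrings::AAString(anchor$peptide),
    type = "overlap", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  qa <- as.character(Biostrings::alignedPattern(pa))
  ra <- as.character(Biostrings::alignedSubject(pa))
  rs <- Biostrings::start(Biostrings::subject(pa))
  qs <- Biostrings::start(Biostrings::pattern(pa))
  L <- nchar(anchor$peptide)
  maps <- vector("list", nrow(peptides))
  for (i in seq_along(maps)) {
    q <- seq_chars(qa[i])
    r <- seq_chars(ra[i])
    r_idx <- cumsum(r != "-") + rs[i] - 1L
    q_idx <- cumsum(q != "-") + qs[i] - 1L
    m <- rep(NA_integer_, L)
    sel <- r != "-" & q != "-"
    m[r_idx[sel]] <- q_idx[sel]
    maps[[i]] <- m
  }
  stats::setNames(maps, peptides$id)
}

pol_type_from_residue <- function(residue) {
  dplyr::case_when(
    residue == "F" ~ "Phe762",
    residue == "Y" ~ "Tyr762",
    residue == "L" ~ "Leu762",
    residue == "unresolved" ~ "Unresolved",
    TRUE ~ "Other"
  )
}

#' Classify peptides at the anchored 762 position
#'
#' Aligns each peptide to the PolA anchor (ends-free global alignment) and
#' reports the query residue mapped to reference position 762. Peptides whose
#' alignment leaves position 762 deleted or outside the aligned span are
#' `unresolved`. The phylogenetic `group` is left `"Unassigned"`; it is filled
#' in later from replisome content ([field_guide_predict()]) or tree context.
#'
#' @param peptides Data frame with columns `id`, `sequence`.
#' @param anchor The PolA [reference_anchor()] (must carry position `pos762`).
#' @param params [align_params()].
#' @param maps Optional precomputed maps from an earlier classification run
#'   (internal use).
#' @return A tibble: `peptide_id`, `residue762`, `pol_type`
#'   (`Phe762`/`Tyr762`/`Leu762`/`Other`/`Unresolved`), `group`, `coverage`
#'   (fraction of anchor residues aligned to query residues).
#' @export
classify_762 <- function(peptides, anchor, params = align_params(), maps = NULL) {
  if (is.null(anchor$positions[["pos762"]])) {
    abort(sprintf("Anchor '%s' lacks the named position 'pos762'.", anchor$name))
  }
  pos <- anchor$positions[["pos762"]]
  if (is.null(maps)) maps <- anchor_maps(peptides, anchor, params)
  res <- map_chr(peptides$id, function(id) {
    m <- maps[[id]]
    qp <- m[pos]
    if (is.na(qp)) "unresolved" else substr(peptides$sequence[match(id, peptides$id)], qp, qp)
  })
  cov <- map_dbl(peptides$id, function(id) mean(!is.na(maps[[id]])))
  tibble(
    peptide_id = peptides$id,
    residue762 = res,
    pol_type = pol_type_from_residue(res),
    group = "Unassigned",
    coverage = cov
  )
}

#' Extract an anchored reference window from a peptide
#'
#' Returns the query residues mapped to the anchor window's positions, in
#' reference order, omitting deleted positions, together with the fraction of
#' window positions that mapped.
#'
#' @param sequence Query peptide sequence.
#' @param anchor A [reference_anchor()].
#' @param window_label Name of a window on the anchor.
#' @param params [align_params()].
#' @return A list with elements `sequence` (extracted region) and `coverage`.
#' @export
extract_window <- function(sequence, anchor, window_label, params = align_params()) {
  w <- anchor$windows[[window_label]]
  if (is.null(w)) abort(sprintf("Anchor '%s' has no window '%s'.", anchor$name, window_label))
  maps <- anchor_maps(tibble(id = "q", sequence = sequence), anchor, params)
  m <- maps[["q"]][w[1]:w[2]]
  mapped <- m[!is.na(m)]
  chars <- seq_chars(sequence)
  list(
    sequence = paste(chars[mapped], collapse = ""),
    coverage = length(mapped) / length(m)
  )
}
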