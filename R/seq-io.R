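#' Read a FASTA file into a tibble
#'
#' Headers are split at the first whitespace to form the record id; the
#' remainder (if any) is kept as `desc`. Sequences are uppercased and validated
#' against the requested alphabet (`N` is tolerated for nucleotide records and
#' `X` for amino-acid records).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @return A tibble with columns `id`, `sequence`, `desc`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some peptide", "MKL", ">b", "acgt"), tf)
#' read_fasta(tf, "amino-acid")[1, ]
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino-acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("FASTA file '%s' does not exist.", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble(id = character(), sequence = character(), desc = character()))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    abort(sprintf("Duplicate FASTA id '%s' in '%s'.", dup[1L], path))
  }
  seqs <- str_to_upper(as.character(set))
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0L) {
    abort(sprintf("Record '%s' has an empty sequence.", ids[empty[1L]]))
  }
  letters <- if (alphabet == "nucleotide") NT_LETTERS else AA_LETTERS
  extra <- if (alphabet == "nucleotide") "N" else "X"
  purrr::walk2(seqs, ids, function(s, i) check_alphabet(s, i, letters, extra))
  tibble(id = unname(ids), sequence = unname(seqs), desc = unname(desc))
}

#' Write records to a FASTA file
#'
#' @param records A data frame with columns `id` and `sequence` (an optional
#'   `desc` column is appended to the header after a space).
#' @param path Output path.
#' @param width Line-wrap width in residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (width < 1) abort("`width` must be >= 1.")
  headers <- records$id
  if ("desc" %in% names(records)) {
    has_desc <- !is.na(records$desc) & nzchar(records$desc)
    headers[has_desc] <- paste(headers[has_desc], records$desc[has_desc])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", headers[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Thin wrappers around [readr::read_tsv()] / [readr::write_tsv()] that fix the
#' pipeline's conventions: a header row, tab separation, no quoting surprises.
#'
#' @param path File path.
#' @param rows A data frame to write.
#' @return `read_tsv_table()` returns a tibble; `write_tsv_table()` returns `path`
#'   invisibly.
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Table '%s' does not exist.", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(rows, path) {
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

# Translate in-frame nucleotides (length trimmed to a codon multiple);
# ambiguous codons (e.g. containing N) become X. Vectorized over sequences.
translate_aa <- function(nt) {
  n <- floor(nchar(nt) / 3) * 3
  out <- character(length(nt))
  ok <- n > 0L
  if (any(ok)) {
    x <- Biostrings::DNAStringSet(substr(nt[ok], 1L, n[ok]))
    out[ok] <- suppressWarnings(as.character(Biostrings::translate(
      x,
      if.fuzzy.codon = "solve", no.init.codon = TRUE
    )))
  }
  unname(out)
}

# ORFs within one forward-frame translation. Returns aa-index start/stop pairs.
frame_orfs <- function(aa, min_len_aa, longest_only) {
  if (!nzchar(aa)) return(NULL)
  chars <- seq_chars(aa)
  starts <- which(chars == "M")
  stops <- which(chars == "*")
  if (length(starts) == 0L || length(stops) == 0L) return(NULL)
  # first stop at or after each start
  idx <- findInterval(starts - 1L, stops) + 1L
  ok <- idx <= length(stops)
  starts <- starts[ok]
  stop_at <- stops[idx[ok]]
  len <- stop_at - starts
  keep <- len >= min_len_aa
  starts <- starts[keep]
  stop_at <- stop_at[keep]
  if (longest_only && length(starts) > 0L) {
    first <- !duplicated(stop_at) # starts ascending => first per stop is leftmost
    starts <- starts[first]
    stop_at <- stop_at[first]
  }
  if (length(starts) == 0L) return(NULL)
  list(start_aa = starts, stop_aa = stop_at)
}

#' Find open reading frames on a contig
#'
#' Scans all six frames for ATG-initiated ORFs under the standard genetic code.
#' The reported nucleotide span runs from the ATG through the stop codon
#' (1-based, inclusive, forward-strand coordinates); the peptide excludes the
#' stop. Overlapping ORFs (nested ATGs sharing a stop) are all reported unless
#' `longest_only = TRUE`, which keeps the leftmost ATG per (frame, stop).
#' Ranks are assigned left-to-right by forward-strand start, irrespective of
#' gene strand.
#'
#' @param sequence Contig nucleotide sequence (A/C/G/T/N).
#' @param contig_id Contig identifier recorded in the output.
#' @param min_len_aa Minimum peptide length in amino acids (>= 1).
#' @param longest_only Keep only the longest ORF per (frame, stop codon).
#' @return A tibble with columns `contig_id`, `rank`, `start`, `end`, `strand`,
#'   `peptide`, `peptide_id`. Empty (zero-row) when no ORF is found.
#' @examples
#' find_orfs("CCATGAAATTTTAGCC", "c1")
#' @export
find_orfs <- function(sequence, contig_id = "contig", min_len_aa = 1, longest_only = FALSE) {
  assert_scalar_string(sequence, "sequence")
  find_orfs_core(contig_id, sequence, min_len_aa, longest_only)
}

# Vectorized six-frame scan shared by find_orfs() and find_orfs_all():
# translation is batched per (strand, frame) across all contigs.
find_orfs_core <- function(ids, sequences, min_len_aa, longest_only) {
  if (min_len_aa < 1) abort("`min_len_aa` must be >= 1.")
  sequences <- str_to_upper(sequences)
  L <- nchar(sequences)
  empty <- tibble(
    contig_id = character(), rank = integer(), start = integer(),
    end = integer(), strand = character(), peptide = character(),
    peptide_id = character()
  )
  keep <- L >= 6L
  if (!any(keep)) return(empty)
  ids <- ids[keep]
  sequences <- sequences[keep]
  L <- L[keep]
  rc <- reverse_complement(sequences)
  rows <- list()
  for (strand in c("+", "-")) {
    s_vec <- if (strand == "+") sequences else rc
    for (f in 1:3) {
      aa_vec <- translate_aa(substr(s_vec, f, nchar(s_vec)))
      for (i in seq_along(aa_vec)) {
        hits <- frame_orfs(aa_vec[i], min_len_aa, longest_only)
        if (is.null(hits)) next
        nt_start <- f + 3L * (hits$start_aa - 1L)
        nt_end <- f + 3L * hits$stop_aa - 1L
        pep <- substring(aa_vec[i], hits$start_aa, hits$stop_aa - 1L)
        if (strand == "-") {
          tmp <- L[i] - nt_end + 1L
          nt_end <- L[i] - nt_start + 1L
          nt_start <- tmp
        }
        rows[[length(rows) + 1L]] <- tibble(
          contig_id = ids[i], start = as.integer(nt_start),
          end = as.integer(nt_end), strand = strand, peptide = pep
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  list_rbind(rows) |>
    arrange(.data$contig_id, .data$start, .data$end, .data$strand) |>
    group_by(.data$contig_id) |>
    mutate(rank = row_number()) |>
    ungroup() |>
    mutate(peptide_id = sprintf("%s_orf%03d", .data$contig_id, .data$rank)) |>
    select("contig_id", "rank", "start", "end", "strand", "peptide", "peptide_id")
}

#' Find ORFs across a set of contigs
#'
#' @param contigs A data frame with columns `id` and `sequence`.
#' @inheritParams find_orfs
#' @return Gene calls from [find_orfs()] for every contig, sorted by
#'   `contig_id` then `rank`.
#' @export
find_orfs_all <- function(contigs, min_len_aa = 1, longest_only = FALSE) {
  stopifnot(is.data.frame(contigs), all(c("id", "sequence") %in% names(contigs)))
  if (anyDuplicated(contigs$id) > 0L) abort("Duplicate contig ids.")
  find_orfs_core(contigs$id, contigs$sequence, min_len_aa, longest_only) |>
    arrange(.data$contig_id, .data$rank)
}
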