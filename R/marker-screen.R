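FAMILY_LABELS <- c(
  "PolA", "Gp4-like", "DnaB-like", "UvrD-like", "RecB-like", "SNF2-like",
  "RecA-like", "RNR-I-Other", "RNR-I-CyanoSP", "RNR-II-Other", "RNR-II-RTPR",
  "DnaG", "MazG"
)

HELICASE_LABELS <- c("Gp4-like", "DnaB-like", "UvrD-like", "RecB-like", "SNF2-like", "RecA-like")
RING_HELICASES <- c("Gp4-like", "DnaB-like")
RNR_LABELS <- c("RNR-I-Other", "RNR-I-CyanoSP", "RNR-II-Other", "RNR-II-RTPR")
ACCESSORY_LABELS <- c("DnaG", "MazG")

POLA_GROUPS <- c("Tyr762", "Phe762-I", "Phe762-II", "Leu762-I", "Leu762-II")
GROUP_RESIDUE <- c(
  "Tyr762" = "Y", "Phe762-I" = "F", "Phe762-II" = "F",
  "Leu762-I" = "L", "Leu762-II" = "L"
)

# Family template lengths (aa). Helicases/accessory genes get independent
# random scaffolds; RNR class templates are derived from the NrdA-like anchor
# scaffold so their rnr_region window stays anchorable; PolA group templates
# are derived from the PolA anchor scaffold with the group's 762 residue
# frozen in.
FAMILY_TEMPLATE_LEN <- c(
  "Gp4-like" = 420L, "DnaB-like" = 450L, "UvrD-like" = 380L,
  "RecB-like" = 400L, "SNF2-like" = 440L, "RecA-like" = 360L,
  "DnaG" = 340L, "MazG" = 260L
)

# Divergence (1 - identity) of derived templates from their parent scaffold.
TEMPLATE_DIVERGENCE <- 0.45

#' Synthetic marker templates
#'
#' Deterministic template peptides for every marker family: one per helicase
#' and accessory family (independent random scaffolds), one per RNR class
#' (derived from the NrdA-like anchor scaffold at 45% divergence, so each
#' class template still anchors to the `rnr_region` window), and one PolA
#' template per 762-group (derived from the PolA anchor scaffold at 45%
#' divergence with residue 762 frozen to the group's residue). These templates
#' seed both the bundled marker panel and the synthetic community generator.
#'
#' @return A named list of peptide strings. PolA group templates are keyed
#'   `PolA:<group>`.
#' @export
family_templates <- function() {
  panel <- anchor_panel()
  out <- list()
  for (i in seq_along(FAMILY_TEMPLATE_LEN)) {
    fam <- names(FAMILY_TEMPLATE_LEN)[i]
    out[[fam]] <- random_peptide(FAMILY_TEMPLATE_LEN[[i]], seed = 100000 + i)
  }
  for (i in seq_along(RNR_LABELS)) {
    out[[RNR_LABELS[i]]] <- mutate_peptide(
      panel$nrda$peptide, 1 - TEMPLATE_DIVERGENCE,
      frozen_positions = 1L, seed = 200000 + i
    )
  }
  pos762 <- panel$pola$positions[["pos762"]]
  for (i in seq_along(POLA_GROUPS)) {
    grp <- POLA_GROUPS[i]
    tmpl <- mutate_peptide(
      panel$pola$peptide, 1 - TEMPLATE_DIVERGENCE,
      frozen_positions = c(1L, pos762), seed = 300000 + i
    )
    chars <- seq_chars(tmpl)
    chars[pos762] <- GROUP_RESIDUE[[grp]]
    out[[paste0("PolA:", grp)]] <- paste(chars, collapse = "")
  }
  out
}

#' Bundled synthetic marker panel
#'
#' One exemplar peptide per marker family, as a tibble. The PolA entry is the
#' anchor scaffold itself; family labels follow the closed vocabulary used
#' throughout the package (helicases `Gp4-like`, `DnaB-like`, `UvrD-like`,
#' `RecB-like`, `SNF2-like`, `RecA-like`; RNR classes `RNR-I-Other`,
#' `RNR-I-CyanoSP`, `RNR-II-Other`, `RNR-II-RTPR`; accessory `DnaG`, `MazG`).
#'
#' @param include_pola_groups Also include the five per-group PolA templates
#'   as additional `PolA` entries (slower screening, slightly higher
#'   sensitivity for diverged PolA fragments).
#' @return A tibble with columns `family`, `id`, `sequence`.
#' @export
marker_panel <- function(include_pola_groups = FALSE) {
  tmpl <- family_templates()
  anchors <- anchor_panel()
  rows <- tibble(
    family = "PolA", id = "PolA_scaffold", sequence = anchors$pola$peptide
  )
  fams <- c(names(FAMILY_TEMPLATE_LEN), RNR_LABELS)
  rows <- bind_rows(rows, tibble(
    family = fams,
    id = paste0(gsub("[^A-Za-z0-9]", "_", fams), "_template"),
    sequence = unlist(tmpl[fams], use.names = FALSE)
  ))
  if (include_pola_groups) {
    keys <- paste0("PolA:", POLA_GROUPS)
    rows <- bind_rows(rows, tibble(
      family = "PolA",
      id = paste0("PolA_", gsub("[^A-Za-z0-9]", "_", POLA_GROUPS), "_template"),
      sequence = unlist(tmpl[keys], use.names = FALSE)
    ))
  }
  rows
}

check_panel <- function(panel) {
  stopifnot(is.data.frame(panel), all(c("family", "id", "sequence") %in% names(panel)))
  bad <- setdiff(unique(panel$family), FAMILY_LABELS)
  if (length(bad) > 0L) {
    abort(sprintf("Unknown marker family label(s): %s", paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Karlin-Altschul E-value estimate
#'
#' `E = K * m * n * exp(-lambda * S)` for a local alignment score `S`, query
#' length `m` and search-space (panel) size `n` in residues.
#'
#' @param score Local alignment score(s).
#' @param m Query length(s) in residues.
#' @param n Search-space size in residues.
#' @param params [align_params()] carrying `K` and `lambda`.
#' @return Numeric E-value estimate(s).
#' @export
karlin_altschul_evalue <- function(score, m, n, params = align_params()) {
  params$K * m * n * exp(-params$lambda * score)
}

# Smith-Waterman scores of many queries against one subject.
local_scores <- function(sequences, subject, params = align_params()) {
  if (length(sequences) == 0L) return(numeric())
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(sequences), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE
  )
}

# Score every peptide against every panel entry. Returns a tibble
# (peptide_id, family, entry_id, score, e_value) with one row per pair;
# E-values use the family's total panel residues as the search space.
panel_scores <- function(peptides, panel, params = align_params()) {
  check_panel(panel)
  fam_n <- panel |>
    group_by(.data$family) |>
    summarise(n_res = sum(nchar(.data$sequence)), .groups = "drop")
  res <- purrr::map(seq_len(nrow(panel)), function(j) {
    tibble(
      peptide_id = peptides$id,
      family = panel$family[j],
      entry_id = panel$id[j],
      subject_len = nchar(panel$sequence[j]),
      score = local_scores(peptides$sequence, panel$sequence[j], params),
      m = nchar(peptides$sequence)
    )
  }) |> list_rbind()
  res |>
    left_join(fam_n, by = "family") |>
    mutate(e_value = karlin_altschul_evalue(.data$score, .data$m, .data$n_res, params)) |>
    select("peptide_id", "family", "entry_id", "subject_len", "score", "e_value")
}

# Fraction of the panel entry covered by the local alignment of each peptide.
subject_coverage <- function(sequences, subject, params = align_params()) {
  if (length(sequences) == 0L) return(numeric())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(sequences), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  w <- Biostrings::end(Biostrings::subject(pa)) - Biostrings::start(Biostrings::subject(pa)) + 1L
  w / nchar(subject)
}

#' Screen peptides for PolA
#'
#' Retains peptides with a local-alignment hit to a `PolA` panel entry at
#' `e_value <= e_cutoff`, length `>= min_len` amino acids, and local-alignment
#' coverage of the panel entry `>= min_coverage` (the offline stand-in for an
#' independent domain-database confirmation).
#'
#' @param peptides Data frame with columns `id`, `sequence`.
#' @param panel Marker panel tibble ([marker_panel()]); must contain at least
#'   one `PolA` entry.
#' @param e_cutoff E-value cutoff (default `1e-5`).
#' @param min_len Minimum peptide length in aa (default 200).
#' @param min_coverage Minimum fraction of the best panel entry covered by the
#'   local alignment (default 0.3).
#' @param params [align_params()].
#' @param scores Optional precomputed [panel_scores()] table to reuse.
#' @return A tibble of retained peptides: `id`, `sequence`, `score`,
#'   `e_value`, `coverage`.
#' @export
screen_pola <- function(peptides, panel, e_cutoff = 1e-5, min_len = 200,
                        min_coverage = 0.3, params = align_params(), scores = NULL) {
  check_panel(panel)
  pola_panel <- panel[panel$family == "PolA", , drop = FALSE]
  if (nrow(pola_panel) == 0L) abort("Marker panel contains no PolA entry.")
  keep_len <- peptides[nchar(peptides$sequence) >= min_len, , drop = FALSE]
  if (nrow(keep_len) == 0L) {
    return(tibble(
      id = character(), sequence = character(), score = numeric(),
      e_value = numeric(), coverage = numeric()
    ))
  }
  if (is.null(scores)) {
    scores <- panel_scores(keep_len, pola_panel, params)
  } else {
    scores <- scores[scores$family == "PolA" & scores$peptide_id %in% keep_len$id, , drop = FALSE]
  }
  best <- scores |>
    group_by(.data$peptide_id) |>
    slice_max(.data$score, n = 1, with_ties = FALSE) |>
    ungroup() |>
    filter(.data$e_value <= e_cutoff)
  if (nrow(best) == 0L) {
    return(tibble(
      id = character(), sequence = character(), score = numeric(),
      e_value = numeric(), coverage = numeric()
    ))
  }
  hits <- keep_len |>
    inner_join(best, by = c(id = "peptide_id"))
  hits <- hits |>
    group_by(.data$entry_id) |>
    group_modify(function(df, key) {
      subj <- pola_panel$sequence[match(key$entry_id, pola_panel$id)]
      df$coverage <- subject_coverage(df$sequence, subj, params)
      df
    }) |>
    ungroup() |>
    filter(.data$coverage >= min_coverage) |>
    select("id", "sequence", "score", "e_value", "coverage")
  hits[order(match(hits$id, peptides$id)), , drop = FALSE]
}

#' Assign a replication-gene family to each peptide
#'
#' Scores each peptide against every panel entry and reports the best-scoring
#' family at or below the E-value cutoff. When the top two *families* score
#' within `ambiguity_margin` (relative to the top score) the peptide is
#' labelled `"ambiguous"`; peptides with no passing hit get `NA`.
#'
#' @inheritParams screen_pola
#' @param ambiguity_margin Relative score margin under which the top two
#'   families are considered indistinguishable (default 0.05).
#' @return A tibble: `peptide_id`, `family` (`NA` = none), `score`, `e_value`.
#'   Output order matches input order; results are invariant to input order
#'   and peptide renaming.
#' @export
assign_family <- function(peptides, panel, e_cutoff = 1e-5,
                          ambiguity_margin = 0.05, params = align_params(),
                          scores = NULL) {
  check_panel(panel)
  if (nrow(peptides) == 0L) {
    return(tibble(peptide_id = character(), family = character(), score = numeric(), e_value = numeric()))
  }
  if (is.null(scores)) scores <- panel_scores(peptides, panel, params)
  per_family <- scores |>
    group_by(.data$peptide_id, .data$family) |>
    slice_max(.data$score, n = 1, with_ties = FALSE) |>
    ungroup()
  calls <- per_family |>
    filter(.data$e_value <= e_cutoff) |>
    group_by(.data$peptide_id) |>
    arrange(desc(.data$score), .data$family, .by_group = TRUE) |>
    summarise(
      family = if (n() > 1 && .data$score[2] >= .data$score[1] * (1 - ambiguity_margin)) {
        "ambiguous"
      } else {
        .data$family[1]
      },
      score = .data$score[1],
      e_value = .data$e_value[1],
      .groups = "drop"
    )
  out <- tibble(peptide_id = peptides$id) |>
    left_join(calls, by = "peptide_id")
  out
}
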