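#' Field-guide prediction of phage group, lifestyle and clade
#'
#' Applies the dichotomous replisome key to each profile, in fixed rule
#' order, with a reproducible rule trace:
#'
#' * **R1** Tyr762 -> group `Tyr762`, lytic; clade candidates from the RNR
#'   class when an RNR is present.
#' * **R2** Phe762 with a DnaB-like helicase -> `Phe762-I`, lytic.
#' * **R3** Phe762, no ring helicase (no Gp4-like/DnaB-like) and any of
#'   RecA-/SNF2-/RecB-/UvrD-like -> `Phe762-II`, indeterminate.
#' * **R4** Leu762 with RecB-like and SNF2-like -> `Leu762-I`, temperate.
#' * **R5** Leu762 with UvrD-like and SNF2-like -> `Leu762-II`, temperate.
#' * **R6** Leu762 otherwise -> group `Unassigned` (temperate-leaning, left
#'   indeterminate; the diagnostic helicase pair is missing).
#'
#' Conflicts flagged (without blocking a rule): an RNR on a Leu762 contig and
#' a Gp4-like helicase on a Leu762 contig, both rare in nature; no rule fired.
#' Lifestyle is `indeterminate` whenever the group is `Unassigned` or
#' `Phe762-II`. The prediction is a pure function of the profile (and the
#' optional clade table).
#'
#' @param profiles A `replisome_profiles` tibble ([profile_contigs()]).
#' @param clades Optional tibble from [resolve_clades()] (`contig_id`,
#'   `clade`, `candidates`); when present, resolved clades narrow the
#'   reported candidate sets.
#' @return A tibble of class `field_guide_prediction`: `contig_id`,
#'   `predicted_group`, `lifestyle`, `clade_candidates` (list column),
#'   `rule_trace`, `conflicts` (comma-separated strings).
#' @export
field_guide_predict <- function(profiles, clades = NULL) {
  rows <- purrr::pmap(
    list(
      profiles$contig_id, profiles$pol_type, profiles$helicases,
      profiles$rnr_class
    ),
    function(cid, pol, helicases, rnr) {
      trace <- character()
      conflicts <- character()
      group <- "Unassigned"
      lifestyle <- "indeterminate"
      ring <- any(RING_HELICASES %in% helicases)
      nonring <- any(c("RecA-like", "SNF2-like", "RecB-like", "UvrD-like") %in% helicases)
      if (pol == "Tyr762") {
        trace <- "R1"
        group <- "Tyr762"
        lifestyle <- "lytic"
      } else if (pol == "Phe762" && "DnaB-like" %in% helicases) {
        trace <- "R2"
        group <- "Phe762-I"
        lifestyle <- "lytic"
      } else if (pol == "Phe762" && !ring && nonring) {
        trace <- "R3"
        group <- "Phe762-II"
        lifestyle <- "indeterminate"
      } else if (pol == "Leu762" && all(c("RecB-like", "SNF2-like") %in% helicases)) {
        trace <- "R4"
        group <- "Leu762-I"
        lifestyle <- "temperate"
      } else if (pol == "Leu762" && all(c("UvrD-like", "SNF2-like") %in% helicases)) {
        trace <- "R5"
        group <- "Leu762-II"
        lifestyle <- "temperate"
      } else if (pol == "Leu762") {
        trace <- "R6"
        group <- "Unassigned"
        lifestyle <- "indeterminate"
      }
      if (pol == "Leu762" && !is.na(rnr)) conflicts <- c(conflicts, "RNR-with-Leu762")
      if (pol == "Leu762" && "Gp4-like" %in% helicases) conflicts <- c(conflicts, "Gp4-with-Leu762")
      if (length(trace) == 0L) conflicts <- c(conflicts, "no-rule-fired")
      candidates <- if (group == "Tyr762" && !is.na(rnr)) {
        assign_clade(rnr, pol)[[1]]
      } else if (group %in% c("Phe762-I", "Phe762-II") && !is.na(rnr)) {
        assign_clade(rnr, pol)[[1]]
      } else {
        integer()
      }
      tibble(
        contig_id = cid, predicted_group = group, lifestyle = lifestyle,
        clade_candidates = list(candidates),
        rule_trace = paste(trace, collapse = ","),
        conflicts = paste(conflicts, collapse = ",")
      )
    }
  )
  out <- list_rbind(rows)
  if (!is.null(clades)) {
    resolved <- clades |>
      filter(!is.na(.data$clade)) |>
      select("contig_id", "clade")
    out <- out |>
      left_join(resolved, by = "contig_id") |>
      mutate(clade_candidates = purrr::map2(
        .data$clade_candidates, .data$clade,
        function(cand, cl) if (!is.na(cl)) as.integer(cl) else cand
      )) |>
      select(-"clade")
  }
  class(out) <- c("field_guide_prediction", class(out))
  out
}
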