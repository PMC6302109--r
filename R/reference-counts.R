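#' Bundled PolA survey count table
#'
#' Published per-library PolA peptide counts (>= 200 aa, conserved 762
#' position) by 762 type, with library counts and total predicted peptides in
#' millions, for the deeply sequenced Chesapeake Bay (SERC) virome and the
#' 86-library global (MgOl) collection. The `normalized_printed` column
#' transcribes the published per-million rates as printed; recompute with
#' [normalize_per_million()].
#'
#' @return A tibble with columns `collection`, `sphere`, `libraries`,
#'   `peptides_millions`, `phe762`, `tyr762`, `leu762`, `total`,
#'   `normalized_printed`.
#' @export
pola_reference_counts <- function() {
  path <- system.file("extdata", "table1_pola_counts.tsv", package = "polatyper")
  read_tsv_table(path)
}

#' PolA rate per million predicted peptides
#'
#' `round(count / peptides_millions)`: the normalization used to compare
#' marker yield across libraries of very different sequencing depth.
#'
#' @param count PolA peptide count(s).
#' @param peptides_millions Total predicted peptides in the library,
#'   in millions.
#' @return Integer rate(s) of PolA peptides per million peptides.
#' @export
normalize_per_million <- function(count, peptides_millions) {
  if (any(peptides_millions <= 0)) abort("`peptides_millions` must be positive.")
  as.integer(round(count / peptides_millions))
}
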