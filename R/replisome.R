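#' Build per-contig replisome profiles
#'
#' Combines per-peptide family assignments with PolA 762 classifications into
#' one row per contig: the PolA call (best-scoring PolA peptide when several
#' overlap), the set of helicase families present, the single best-scoring
#' RNR class, and accessory replication genes. Presence is contig-level (the
#' primary statistic); gene order is retained in `gene_order` for adjacency
#' summaries.
#'
#' @param gene_calls Tibble with columns `contig_id`, `peptide_id`, `rank`.
#' @param families Tibble from [assign_family()] (`peptide_id`, `family`,
#'   `score`).
#' @param classifications Tibble from [classify_762()] (`peptide_id`,
#'   `residue762`, `pol_type`). Only peptides that passed the PolA screen
#'   should appear here.
#' @return A tibble of class `replisome_profiles`: `contig_id`, `peptide_id`
#'   (PolA), `residue762`, `pol_type`, `group` (filled by
#'   [field_guide_predict()]), `helicases` / `accessory` (list columns,
#'   sorted), `rnr_class`, `combination` (sorted labels, RNR collapsed to
#'   `"RNR"`), `gene_order` (list column of `(rank, family)`).
#' @export
profile_contigs <- function(gene_calls, families, classifications) {
  stopifnot(all(c("contig_id", "peptide_id", "rank") %in% names(gene_calls)))
  ann <- gene_calls |>
    left_join(families, by = "peptide_id") |>
    left_join(classifications, by = "peptide_id")
  pola <- ann |>
    filter(!is.na(.data$pol_type)) |>
    group_by(.data$contig_id) |>
    arrange(desc(.data$score), .data$peptide_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  no_pola <- setdiff(unique(gene_calls$contig_id), pola$contig_id)
  if (length(no_pola) > 0L) {
    abort(sprintf(
      "Contig(s) without a verified PolA classification (screen first): %s",
      paste(utils::head(no_pola, 3), collapse = ", ")
    ))
  }
  per_contig <- ann |>
    filter(!is.na(.data$family), .data$family != "ambiguous") |>
    group_by(.data$contig_id) |>
    summarise(
      helicases = list(sort(unique(intersect(.data$family, HELICASE_LABELS)))),
      accessory = list(sort(unique(intersect(.data$family, ACCESSORY_LABELS)))),
      rnr_class = {
        r <- .data$family %in% RNR_LABELS
        if (any(r)) .data$family[r][which.max(.data$score[r])] else NA_character_
      },
      gene_order = {
        r <- .data$rank
        f <- .data$family
        list(tibble(rank = r, family = f))
      },
      .groups = "drop"
    )
  out <- pola |>
    select("contig_id", "peptide_id", "residue762", "pol_type") |>
    left_join(per_contig, by = "contig_id") |>
    mutate(
      helicases = purrr::map(.data$helicases, function(h) h %||% character()),
      accessory = purrr::map(.data$accessory, function(a) a %||% character()),
      group = "Unassigned",
      combination = purrr::pmap_chr(
        list(.data$helicases, .data$accessory, .data$rnr_class),
        function(h, a, r) paste(sort(c(h, a, if (!is.na(r)) "RNR")), collapse = "+")
      )
    ) |>
    select(
      "contig_id", "peptide_id", "residue762", "pol_type", "group",
      "helicases", "accessory", "rnr_class", "combination", "gene_order"
    ) |>
    arrange(.data$contig_id)
  class(out) <- c("replisome_profiles", class(out))
  out
}

#' Gene prevalence and co-occurrence per group
#'
#' For each group, the percentage of contigs carrying each gene label
#' (helicase families, accessory genes, each RNR class, and the `RNR`
#' aggregate), plus co-occurrence rows for requested label pairs
#' (`"A+B"` = contigs carrying both).
#'
#' @param profiles A `replisome_profiles` tibble.
#' @param group_col Column to group by (default `"group"`; `"pol_type"` also
#'   useful).
#' @param pairs List of character pairs for co-occurrence rows (default
#'   `Gp4-like` with `RNR`).
#' @return A tibble of class `pola_prevalence`: `group`, `gene`, `count`,
#'   `n_contigs`, `percent`. Empty groups are omitted with a warning.
#' @export
group_gene_prevalence <- function(profiles, group_col = "group",
                                  pairs = list(c("Gp4-like", "RNR"))) {
  stopifnot(group_col %in% names(profiles))
  has_gene <- function(prof_row_genes, g) g %in% prof_row_genes
  flat <- profiles |>
    mutate(
      .group = .data[[group_col]],
      gene_set = purrr::pmap(
        list(.data$helicases, .data$accessory, .data$rnr_class),
        function(h, a, r) c(h, a, if (!is.na(r)) c(r, "RNR"))
      )
    )
  if (nrow(flat) == 0L) {
    warn("No profiles supplied; empty prevalence table.")
    return(tibble(group = character(), gene = character(), count = integer(),
      n_contigs = integer(), percent = numeric()))
  }
  sizes <- flat |> count(.data$.group, name = "n_contigs")
  singles <- flat |>
    select(".group", "gene_set") |>
    tidyr::unnest_longer("gene_set", values_to = "gene") |>
    count(.data$.group, .data$gene, name = "count")
  pair_rows <- purrr::map(pairs, function(pr) {
    flat |>
      mutate(both = purrr::map_lgl(.data$gene_set, function(g) all(pr %in% g))) |>
      group_by(.data$.group) |>
      summarise(count = sum(.data$both), .groups = "drop") |>
      mutate(gene = paste(pr, collapse = "+"))
  }) |> list_rbind()
  out <- bind_rows(singles, pair_rows) |>
    left_join(sizes, by = ".group") |>
    mutate(percent = 100 * .data$count / .data$n_contigs) |>
    rename(group = ".group") |>
    arrange(.data$group, .data$gene)
  class(out) <- c("pola_prevalence", class(out))
  out
}

#' Assign reads to contigs by exact substring match
#'
#' A read is assigned to a contig when the read or its reverse complement
#' occurs as an exact substring of that contig and of no other contig; reads
#' matching several contigs are left unassigned (`n_contigs` > 1), as are
#' reads matching none. Deterministic and order-independent.
#'
#' @param reads Data frame with columns `id`, `sequence` (A/C/G/T).
#' @param contigs Data frame with columns `id`, `sequence`.
#' @return A tibble `read_id`, `contig_id` (`NA` unless exactly one match),
#'   `n_contigs` (distinct contigs matched).
#' @export
recruit_reads_exact <- function(reads, contigs) {
  stopifnot(all(c("id", "sequence") %in% names(reads)), all(c("id", "sequence") %in% names(contigs)))
  if (nrow(reads) == 0L) {
    return(tibble(read_id = character(), contig_id = character(), n_contigs = integer()))
  }
  n <- nrow(reads)
  n_hits <- integer(n)
  first_hit <- integer(n)
  subjects <- Biostrings::DNAStringSet(contigs$sequence)
  fixed_width <- length(unique(nchar(reads$sequence))) == 1L
  if (fixed_width) {
    pd_f <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence))
    pd_r <- Biostrings::PDict(Biostrings::DNAStringSet(reverse_complement(reads$sequence)))
  } else {
    rc <- reverse_complement(reads$sequence)
  }
  for (j in seq_along(subjects)) {
    if (fixed_width) {
      h <- (Biostrings::countPDict(pd_f, subjects[[j]]) +
        Biostrings::countPDict(pd_r, subjects[[j]])) > 0L
    } else {
      h <- vapply(seq_len(n), function(i) {
        Biostrings::countPattern(reads$sequence[i], subjects[[j]]) > 0L ||
          Biostrings::countPattern(rc[i], subjects[[j]]) > 0L
      }, logical(1))
    }
    idx <- which(h)
    if (length(idx) > 0L) {
      fresh <- idx[first_hit[idx] == 0L]
      n_hits[idx] <- n_hits[idx] + 1L
      first_hit[fresh] <- j
    }
  }
  hit_id <- ifelse(n_hits == 1L, contigs$id[ifelse(first_hit == 0L, NA, first_hit)], NA_character_)
  tibble(read_id = reads$id, contig_id = hit_id, n_contigs = n_hits)
}

#' Read-mass share per PolA + replication-gene combination
#'
#' Fraction of uniquely recruited reads landing on contigs with each
#' (group, gene combination) cell, over all reads assigned to profiled
#' contigs. Fractions sum to 1.
#'
#' @param profiles A `replisome_profiles` tibble (with `group` filled in).
#' @param assignments Tibble from [recruit_reads_exact()] or an external
#'   mapper (`read_id`, `contig_id`).
#' @return A tibble of class `pola_abundance`: `group`, `combination`,
#'   `reads`, `fraction`, sorted by decreasing fraction.
#' @export
combination_abundance <- function(profiles, assignments) {
  assigned <- assignments |>
    filter(!is.na(.data$contig_id), .data$contig_id %in% profiles$contig_id)
  if (nrow(assigned) == 0L) abort("No reads assigned to profiled contigs.")
  out <- assigned |>
    count(.data$contig_id, name = "reads") |>
    left_join(profiles |> select("contig_id", "group", "combination"), by = "contig_id") |>
    group_by(.data$group, .data$combination) |>
    summarise(reads = sum(.data$reads), .groups = "drop") |>
    mutate(fraction = .data$reads / sum(.data$reads)) |>
    arrange(desc(.data$fraction), .data$group, .data$combination)
  class(out) <- c("pola_abundance", class(out))
  out
}
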