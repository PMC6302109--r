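#' Mutate a peptide to a target identity
#'
#' Substitutes residues at `round((1 - target_identity) * nchar(template))`
#' distinct non-frozen positions, each replaced by a uniformly drawn
#' *different* residue, so the realized identity is `1 - n_sub / L` (within
#' 0.5/L of the target; for templates of 25 aa and up this is inside the
#' +/- 0.02 contract). Frozen positions are never touched.
#'
#' @param template Peptide string.
#' @param target_identity Target fractional identity in (0, 1].
#' @param frozen_positions Integer positions that must not change.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return The mutated peptide string.
#' @export
mutate_peptide <- function(template, target_identity, frozen_positions = integer(), seed = NULL) {
  assert_scalar_string(template, "template")
  if (!is.numeric(target_identity) || target_identity <= 0 || target_identity > 1) {
    abort("`target_identity` must be in (0, 1].")
  }
  L <- nchar(template)
  if (length(frozen_positions) > 0L && (min(frozen_positions) < 1 || max(frozen_positions) > L)) {
    abort("`frozen_positions` outside the template.")
  }
  n_sub <- round((1 - target_identity) * L)
  free <- setdiff(seq_len(L), frozen_positions)
  if (n_sub > length(free)) {
    abort(sprintf(
      "Target identity %.2f requires %d substitutions but only %d positions are free.",
      target_identity, n_sub, length(free)
    ))
  }
  run <- function() {
    if (n_sub == 0L) return(template)
    chars <- seq_chars(template)
    pos <- if (length(free) == 1L) free else sample(free, n_sub)
    repl <- sample(AA_LETTERS, n_sub, replace = TRUE)
    clash <- repl == chars[pos]
    while (any(clash)) {
      repl[clash] <- sample(AA_LETTERS, sum(clash), replace = TRUE)
      clash <- repl == chars[pos]
    }
    chars[pos] <- repl
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Reverse-translate a peptide into an ORF
#'
#' Emits an ATG-initiated, TAA-terminated open reading frame whose translation
#' is exactly the input peptide, drawing codons uniformly among synonymous
#' options. The peptide must start with methionine.
#'
#' @param peptide Peptide string starting with `M`, no stops.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return A nucleotide string of length `3 * (nchar(peptide) + 1)`.
#' @export
reverse_translate <- function(peptide, seed = NULL) {
  assert_scalar_string(peptide, "peptide")
  if (substr(peptide, 1, 1) != "M") abort("ORF peptides must start with 'M' (ATG-initiated).")
  check_alphabet(peptide, "peptide", AA_LETTERS, character())
  tab <- codon_table()
  run <- function() {
    chars <- seq_chars(peptide)
    codons <- character(length(chars))
    for (aa in unique(chars)) {
      idx <- which(chars == aa)
      opts <- tab[[aa]]
      codons[idx] <- opts[sample.int(length(opts), length(idx), replace = TRUE)]
    }
    codons[1] <- "ATG"
    paste0(paste(codons, collapse = ""), "TAA")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

random_nt <- function(n) paste(sample(NT_LETTERS, n, replace = TRUE), collapse = "")

#' Build a synthetic community specification
#'
#' A community spec fixes the statistical structure the generator emulates:
#' per-population contig counts, the population's 762 residue, gene-presence
#' probabilities (drawn independently per gene; `"RNR"` presence is drawn
#' first, then a class from `rnr_class_probs`), sequence divergences, and an
#' optional read-abundance vector over (group x gene-combination) cells.
#'
#' @param populations Tibble with columns `name`, `n_contigs`, `residue`
#'   (one of F/Y/L), `pola_template`, `gene_probs` (list column of named
#'   probabilities over helicase/accessory labels plus `"RNR"`),
#'   `rnr_class_probs` (list column of named probabilities over the four RNR
#'   classes), and optionally `clade` (integer) and `rnr_template` (list
#'   column of per-class template overrides).
#' @param divergence Within-population divergence (1 - identity) of each gene
#'   instance from its template.
#' @param abundance Optional tibble with columns `group`, `genes`
#'   (list column: character vector of gene labels, RNR collapsed to
#'   `"RNR"`), `share` (summing to 1 including one `"other"` row whose
#'   `genes` is `NA`).
#' @param read_length,n_reads Read geometry for the error-free read simulator.
#' @param spacer_range Intergenic spacer length range (nt).
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(populations, divergence = 0.15, abundance = NULL,
                           read_length = 150, n_reads = 0,
                           spacer_range = c(20, 100)) {
  stopifnot(is.data.frame(populations))
  need <- c("name", "n_contigs", "residue", "pola_template", "gene_probs", "rnr_class_probs")
  missing_cols <- setdiff(need, names(populations))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`populations` lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  for (p in populations$gene_probs) {
    if (length(p) > 0L) {
      stopifnot(all(p >= 0 & p <= 1))
      bad <- setdiff(names(p), c(HELICASE_LABELS, ACCESSORY_LABELS, "RNR"))
      if (length(bad)) abort(sprintf("Unknown gene label(s) in gene_probs: %s", paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(abundance)) {
    stopifnot(all(c("group", "genes", "share") %in% names(abundance)))
    if (abs(sum(abundance$share) - 1) > 1e-9) abort("Abundance shares must sum to 1.")
  }
  structure(
    list(
      populations = as_tibble(populations), divergence = divergence,
      abundance = if (is.null(abundance)) NULL else as_tibble(abundance),
      read_length = as.integer(read_length), n_reads = as.integer(n_reads),
      spacer_range = as.integer(spacer_range)
    ),
    class = "community_spec"
  )
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(
    "<community_spec> %d populations, %d contigs, %d reads (length %d)\n",
    nrow(x$populations), sum(x$populations$n_contigs), x$n_reads, x$read_length
  ))
  invisible(x)
}

fig2_gene_probs <- function() {
  list(
    "Tyr762" = c("Gp4-like" = 0.69, "RNR" = 0.40),
    "Phe762-I" = c("DnaB-like" = 0.60, "SNF2-like" = 0.13, "RNR" = 0.41),
    "Phe762-II" = c("RecA-like" = 0.17, "SNF2-like" = 0.10, "RecB-like" = 0.05, "UvrD-like" = 0.07),
    "Leu762-I" = c("RecB-like" = 0.70, "SNF2-like" = 0.55),
    "Leu762-II" = c("SNF2-like" = 0.45, "UvrD-like" = 0.68)
  )
}

fig2_rnr_class_probs <- function() {
  list(
    "Tyr762" = c("RNR-I-Other" = 0.30, "RNR-I-CyanoSP" = 0.15, "RNR-II-RTPR" = 0.40, "RNR-II-Other" = 0.15),
    "Phe762-I" = c("RNR-I-Other" = 0.35, "RNR-II-RTPR" = 0.35, "RNR-II-Other" = 0.30),
    "Phe762-II" = c("RNR-I-Other" = 1),
    "Leu762-I" = c("RNR-II-Other" = 1),
    "Leu762-II" = c("RNR-II-Other" = 1)
  )
}

FIG2_GROUP_SIZES <- c(
  "Tyr762" = 289L, "Phe762-I" = 124L, "Phe762-II" = 42L,
  "Leu762-I" = 119L, "Leu762-II" = 247L
)

#' Bundled gene-neighbour community configuration
#'
#' The package's reference synthetic-community configuration: the five PolA
#' 762-groups at their observed contig counts, each with its printed
#' gene-presence percentages, plus the printed read-mass shares for the three
#' dominant PolA + replication-gene combinations (Tyr762 + Gp4-like helicase
#' 28.4%, Leu762 Group II + SNF2-like + UvrD-like 16.4%, Phe762 Group I +
#' DnaB-like 13.3%; all remaining mass on the remaining contigs).
#'
#' @param groups Which 762-groups to include (default all five).
#' @param n_contigs Named override of per-group contig counts.
#' @param n_reads Total error-free reads to simulate (0 = none).
#' @param read_length Read length in nt.
#' @param with_abundance Attach the combination-abundance vector (requires all
#'   three named combinations' groups to be present).
#' @return A [community_spec()].
#' @export
serc_fig2_spec <- function(groups = POLA_GROUPS, n_contigs = NULL,
                           n_reads = 0, read_length = 150,
                           with_abundance = FALSE) {
  stopifnot(all(groups %in% POLA_GROUPS))
  sizes <- FIG2_GROUP_SIZES[groups]
  if (!is.null(n_contigs)) sizes[names(n_contigs)] <- as.integer(n_contigs)
  tmpl <- family_templates()
  gp <- fig2_gene_probs()
  rp <- fig2_rnr_class_probs()
  populations <- tibble(
    name = groups,
    n_contigs = unname(sizes),
    residue = unname(GROUP_RESIDUE[groups]),
    pola_template = unname(unlist(tmpl[paste0("PolA:", groups)])),
    gene_probs = unname(gp[groups]),
    rnr_class_probs = unname(rp[groups])
  )
  abundance <- NULL
  if (with_abundance) {
    abundance <- tibble(
      group = c("Tyr762", "Leu762-II", "Phe762-I", "other"),
      genes = list(c("Gp4-like"), c("SNF2-like", "UvrD-like"), c("DnaB-like"), NA_character_),
      share = c(0.284, 0.164, 0.133, 1 - 0.284 - 0.164 - 0.133)
    )
    if (!all(c("Tyr762", "Leu762-II", "Phe762-I") %in% groups)) {
      abort("The bundled abundance vector needs groups Tyr762, Leu762-II and Phe762-I present.")
    }
  }
  community_spec(populations, divergence = 0.15, abundance = abundance,
    read_length = read_length, n_reads = n_reads)
}

# Printed constraints: 140 PolA+RNR contigs; clade 1 = 13 contigs
# (11 Tyr / 1 Phe / 1 Leu); 762-type shares ~70/28/2; RNR class shares
# ~28/10/46/18. The per-clade allocation below satisfies those constraints.
fig4_clade_rows <- function() tibble::tibble(
  clade = c(1L, 1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
  n_contigs = c(11L, 1L, 1L, 15L, 14L, 10L, 14L, 42L, 20L, 7L, 5L),
  residue = c("Y", "F", "L", "Y", "Y", "F", "Y", "Y", "F", "Y", "F"),
  rnr_class = c(
    "RNR-II-Other", "RNR-II-Other", "RNR-II-Other",
    "RNR-I-Other", "RNR-I-Other", "RNR-I-Other",
    "RNR-I-CyanoSP", "RNR-II-RTPR", "RNR-II-RTPR",
    "RNR-II-Other", "RNR-II-Other"
  )
)

#' Bundled concatenated-tree (clade) community configuration
#'
#' A 140-contig community in which every contig carries both a full-length
#' PolA and an RNR gene, allocated across the nine clades defined by the
#' (RNR class x PolA 762-type) combinations. Each clade gets its own PolA and
#' RNR sub-templates (derived from the parent group/class templates at
#' `clade_divergence`), and members diverge from the clade templates at
#' `divergence`, so clades are recoverable both by marker combination and by
#' tree proximity.
#'
#' @param divergence Within-clade member divergence (default 0.10).
#' @param clade_divergence Clade-template divergence from the parent group /
#'   RNR-class template (default 0.20).
#' @param n_scale Multiply every clade's contig count (useful for larger
#'   recovery experiments).
#' @return A [community_spec()] whose populations carry `clade` and
#'   `rnr_template` columns.
#' @export
serc_fig4_spec <- function(divergence = 0.10, clade_divergence = 0.20, n_scale = 1) {
  tmpl <- family_templates()
  panel <- anchor_panel()
  pos762 <- panel$pola$positions[["pos762"]]
  rows <- fig4_clade_rows()
  residue_group <- c(Y = "Tyr762", F = "Phe762-I", L = "Leu762-I")
  pops <- purrr::pmap(rows, function(clade, n_contigs, residue, rnr_class) {
    grp <- residue_group[[residue]]
    pola_t <- mutate_peptide(
      tmpl[[paste0("PolA:", grp)]], 1 - clade_divergence,
      frozen_positions = c(1L, pos762), seed = 400000 + clade * 10 + match(residue, c("Y", "F", "L"))
    )
    rnr_t <- mutate_peptide(
      tmpl[[rnr_class]], 1 - clade_divergence,
      frozen_positions = 1L, seed = 500000 + clade
    )
    tibble(
      name = sprintf("clade%d_%s", clade, residue),
      clade = clade,
      n_contigs = as.integer(ceiling(n_contigs * n_scale)),
      residue = residue,
      pola_template = pola_t,
      gene_probs = list(c("RNR" = 1)),
      rnr_class_probs = list(stats::setNames(1, rnr_class)),
      rnr_template = list(stats::setNames(list(rnr_t), rnr_class))
    )
  }) |> list_rbind()
  community_spec(pops, divergence = divergence)
}

#' Labelled clade references for tree-based resolution
#'
#' One labelled reference per clade population: the clade's PolA and RNR
#' templates, usable as `clade_references` in [run_pipeline()] so that
#' multi-candidate clade assignments (clades 2/3 and 1/8/9, which share an
#' RNR class and 762 type) can be resolved by tree proximity.
#'
#' @param spec A clade-mode [community_spec()] (default [serc_fig4_spec()]).
#' @return A tibble `id`, `pola_sequence`, `rnr_sequence`, `clade`.
#' @export
clade_reference_table <- function(spec = serc_fig4_spec()) {
  pops <- spec$populations
  if (!all(c("clade", "rnr_template") %in% names(pops))) {
    abort("`spec` is not a clade-mode community spec.")
  }
  tibble(
    id = paste0("ref_", pops$name),
    pola_sequence = pops$pola_template,
    rnr_sequence = map_chr(pops$rnr_template, function(x) x[[1]]),
    clade = pops$clade
  )
}

#' Generate a synthetic virioplankton community
#'
#' Emits contigs (each carrying one PolA ORF plus replisome ORFs drawn per the
#' spec's presence probabilities, separated by random intergenic spacers),
#' the true gene calls and peptides, error-free reads sampled as exact
#' substrings with combination-level abundance control, and a ground-truth
#' table. Identical `spec` + `seed` give byte-identical output.
#'
#' @param spec A [community_spec()].
#' @param seed Mandatory integer seed.
#' @return A list of class `pola_community`: `contigs`, `genes`, `peptides`,
#'   `reads`, `truth`, `spec`, `seed`.
#' @export
generate_community <- function(spec, seed) {
  stopifnot(inherits(spec, "community_spec"))
  if (missing(seed)) abort("`seed` is mandatory.")
  tmpl <- family_templates()
  with_seed(seed, {
    contigs <- list()
    genes <- list()
    truth <- list()
    for (p in seq_len(nrow(spec$populations))) {
      pop <- spec$populations[p, ]
      probs <- pop$gene_probs[[1]]
      rnr_probs <- pop$rnr_class_probs[[1]]
      rnr_overrides <- if ("rnr_template" %in% names(spec$populations)) pop$rnr_template[[1]] else NULL
      for (k in seq_len(pop$n_contigs)) {
        cid <- sprintf("%s_c%04d", gsub("[^A-Za-z0-9]", "", pop$name), k)
        frozen <- if (nchar(pop$pola_template) >= 762L) c(1L, 762L) else 1L
        pola_pep <- mutate_peptide(
          pop$pola_template, 1 - spec$divergence,
          frozen_positions = frozen
        )
        drawn <- names(probs)[stats::runif(length(probs)) < probs]
        rnr_class <- NA_character_
        gene_peps <- list(PolA = pola_pep)
        for (g in setdiff(drawn, "RNR")) {
          gene_peps[[g]] <- mutate_peptide(tmpl[[g]], 1 - spec$divergence, frozen_positions = 1L)
        }
        if ("RNR" %in% drawn) {
          rnr_class <- if (length(rnr_probs) == 1L) names(rnr_probs) else {
            sample(names(rnr_probs), 1L, prob = rnr_probs)
          }
          base <- if (!is.null(rnr_overrides) && !is.null(rnr_overrides[[rnr_class]])) {
            rnr_overrides[[rnr_class]]
          } else {
            tmpl[[rnr_class]]
          }
          gene_peps[[rnr_class]] <- mutate_peptide(base, 1 - spec$divergence, frozen_positions = 1L)
        }
        spacer_len <- function() sample(spec$spacer_range[1]:spec$spacer_range[2], 1L)
        seq_parts <- character()
        pos <- 0L
        gene_rows <- list()
        for (gi in seq_along(gene_peps)) {
          sp <- random_nt(spacer_len())
          seq_parts <- c(seq_parts, sp)
          pos <- pos + nchar(sp)
          orf <- reverse_translate(gene_peps[[gi]])
          gene_rows[[gi]] <- tibble(
            contig_id = cid, rank = gi, start = pos + 1L,
            end = pos + nchar(orf), strand = "+",
            family = names(gene_peps)[gi], peptide = gene_peps[[gi]],
            peptide_id = sprintf("%s_g%d", cid, gi)
          )
          seq_parts <- c(seq_parts, orf)
          pos <- pos + nchar(orf)
        }
        seq_parts <- c(seq_parts, random_nt(spacer_len()))
        contig_seq <- paste(seq_parts, collapse = "")
        helicases <- sort(intersect(names(gene_peps), HELICASE_LABELS))
        accessory <- sort(intersect(names(gene_peps), ACCESSORY_LABELS))
        combo <- paste(sort(c(helicases, accessory, if (!is.na(rnr_class)) "RNR")), collapse = "+")
        contigs[[length(contigs) + 1L]] <- tibble(
          id = cid, sequence = contig_seq, source_tag = pop$name
        )
        genes[[length(genes) + 1L]] <- list_rbind(gene_rows)
        truth[[length(truth) + 1L]] <- tibble(
          contig_id = cid, group = pop$name, residue762 = pop$residue,
          clade = if ("clade" %in% names(pop)) pop$clade else NA_integer_,
          genes = paste(sort(setdiff(names(gene_peps), "PolA")), collapse = "+"),
          rnr_class = rnr_class, combination = combo
        )
      }
    }
    contigs <- list_rbind(contigs)
    genes <- list_rbind(genes)
    truth <- list_rbind(truth)
    peptides <- genes |>
      transmute(id = .data$peptide_id, sequence = .data$peptide,
        contig_id = .data$contig_id, family_truth = .data$family)
    reads <- generate_reads(spec, contigs, truth)
    truth <- truth |>
      left_join(
        reads |> count(.data$contig_id, name = "read_count"),
        by = "contig_id"
      ) |>
      mutate(read_count = tidyr::replace_na(.data$read_count, 0L))
    structure(
      list(contigs = contigs, genes = genes, peptides = peptides,
        reads = reads, truth = truth, spec = spec, seed = as.integer(seed)),
      class = "pola_community"
    )
  })
}

# Sample error-free reads as exact substrings. Each read first draws an
# abundance cell (a named group x gene-combination, or "other"), then a
# uniform contig within the cell, a uniform start, and a uniform strand.
generate_reads <- function(spec, contigs, truth) {
  empty <- tibble(id = character(), sequence = character(), contig_id = character())
  if (spec$n_reads <= 0L) return(empty)
  rl <- spec$read_length
  if (any(nchar(contigs$sequence) < rl)) abort("Read length exceeds a contig length.")
  if (is.null(spec$abundance)) {
    cells <- list(seq_len(nrow(contigs)))
    shares <- 1
  } else {
    ab <- spec$abundance
    combo_of <- function(genes) paste(sort(genes), collapse = "+")
    assigned <- rep(FALSE, nrow(contigs))
    cells <- list()
    named <- which(ab$group != "other")
    for (j in named) {
      want <- combo_of(ab$genes[[j]])
      hit <- which(truth$group == ab$group[j] & truth$combination == want)
      if (length(hit) == 0L) {
        abort(sprintf(
          "No contig realizes abundance cell %s x {%s}; infeasible spec/seed.",
          ab$group[j], want
        ))
      }
      cells[[length(cells) + 1L]] <- hit
      assigned[hit] <- TRUE
    }
    other <- which(!assigned)
    if (any(ab$group == "other")) {
      if (length(other) == 0L) abort("No contigs left for the 'other' abundance cell.")
      cells[[length(cells) + 1L]] <- other
    }
    shares <- c(ab$share[named], if (any(ab$group == "other")) ab$share[ab$group == "other"])
  }
  counts <- as.vector(stats::rmultinom(1L, spec$n_reads, shares))
  rows <- list()
  serial <- 0L
  for (j in seq_along(cells)) {
    if (counts[j] == 0L) next
    pick <- cells[[j]][sample.int(length(cells[[j]]), counts[j], replace = TRUE)]
    lens <- nchar(contigs$sequence[pick])
    starts <- floor(stats::runif(counts[j]) * (lens - rl + 1)) + 1L
    s <- substring(contigs$sequence[pick], starts, starts + rl - 1L)
    flip <- stats::runif(counts[j]) < 0.5
    s[flip] <- reverse_complement(s[flip])
    rows[[length(rows) + 1L]] <- tibble(
      contig_id = contigs$id[pick], sequence = s
    )
    serial <- serial + counts[j]
  }
  out <- list_rbind(rows)
  out |>
    mutate(id = sprintf("read%06d", row_number())) |>
    select("id", "sequence", "contig_id")
}

#' @export
print.pola_community <- function(x, ...) {
  cat(sprintf(
    "<pola_community> %d contigs, %d genes, %d reads (seed %d)\n",
    nrow(x$contigs), nrow(x$genes), nrow(x$reads), x$seed
  ))
  invisible(x)
}

#' Write a community to disk
#'
#' Emits `contigs.fasta`, `peptides.fasta`, `reads.fasta` (when present),
#' `genes.tsv` and `truth.tsv` under `dir`.
#'
#' @param community A `pola_community` from [generate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  stopifnot(inherits(community, "pola_community"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(community$contigs, file.path(dir, "contigs.fasta"))
  write_fasta(community$peptides, file.path(dir, "peptides.fasta"))
  if (nrow(community$reads) > 0L) {
    write_fasta(community$reads, file.path(dir, "reads.fasta"))
  }
  write_tsv_table(community$genes |> select(-"peptide"), file.path(dir, "genes.tsv"))
  write_tsv_table(community$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
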