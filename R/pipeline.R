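#' Pipeline configuration
#'
#' Thresholds for the end-to-end analysis. Defaults follow the study design
#' this pipeline reproduces: PolA screen at E <= 1e-5 and >= 200 aa,
#' all-vs-all homology graph at E <= 1e-20, clustering at 75% amino-acid
#' identity (furthest neighbour), core-gene threshold at half the clade's
#' contigs, anchored-window coverage >= 0.8 for tree building, and ten
#' bootstrap replicates.
#'
#' @param e_cutoff_screen,e_cutoff_graph E-value cutoffs for the PolA screen
#'   and the all-vs-all homology graph.
#' @param min_len Minimum PolA peptide length (aa).
#' @param aai_cutoff Amino-acid identity threshold for clustering (0.75 =
#'   cluster at distance <= 0.25).
#' @param core_fraction Core-gene contig fraction per clade.
#' @param window_coverage Minimum anchored-window coverage for tree rows.
#' @param min_orf_len Minimum ORF peptide length (aa) emitted by gene
#'   calling; 150 suppresses spurious random-frame ORFs while every marker
#'   family template is far longer.
#' @param bootstrap_reps Bootstrap replicates for tree supports.
#' @param seed Seed for the (only) stochastic stage, bootstrap resampling.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(e_cutoff_screen = 1e-5, e_cutoff_graph = 1e-20,
                            min_len = 200, aai_cutoff = 0.75,
                            core_fraction = 0.5, window_coverage = 0.8,
                            min_orf_len = 150, bootstrap_reps = 10, seed = 1) {
  stopifnot(
    e_cutoff_screen > 0, e_cutoff_graph > 0, min_len >= 1,
    aai_cutoff > 0, aai_cutoff <= 1, core_fraction > 0, core_fraction <= 1,
    window_coverage >= 0, window_coverage <= 1, min_orf_len >= 1,
    bootstrap_reps >= 1
  )
  structure(
    list(
      e_cutoff_screen = e_cutoff_screen, e_cutoff_graph = e_cutoff_graph,
      min_len = min_len, aai_cutoff = aai_cutoff,
      core_fraction = core_fraction, window_coverage = window_coverage,
      min_orf_len = min_orf_len, bootstrap_reps = bootstrap_reps,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[polatyper] ", fmt), ...))
}

#' Run the full contig analysis pipeline
#'
#' Orchestrates gene calling, PolA screening, 762 classification, family
#' assignment, replisome profiling, field-guide prediction, 75%-identity
#' clustering with a bootstrapped NJ tree of cluster representatives,
#' concatenated PolA+RNR clade assignment, optional read-recruitment
#' abundance, and optional per-clade core-gene clusters. Identical inputs,
#' config and seed give identical outputs.
#'
#' @param contigs Data frame with columns `id`, `sequence` (nucleotide).
#'   Alternatively supply `gene_calls` directly and pass `contigs = NULL`.
#' @param reads Optional reads (`id`, `sequence`) for abundance estimation,
#'   or a precomputed assignment table (`read_id`, `contig_id`).
#' @param config A [pipeline_config()].
#' @param panel Marker panel (default [marker_panel()]).
#' @param anchors Anchor panel (default [anchor_panel()]).
#' @param gene_calls Optional precomputed gene calls
#'   (`contig_id, rank, start, end, strand, peptide, peptide_id`), bypassing
#'   the ORF finder.
#' @param clade_references Optional labelled references for tree-based clade
#'   resolution: tibble `id`, `pola_sequence`, `rnr_sequence`, `clade`.
#' @param compute_core Also build the all-vs-all homology graph and per-clade
#'   core clusters (quadratic in peptide count; off by default).
#' @param out_dir Optional directory; when given, every artifact is written
#'   as TSV/FASTA/Newick.
#' @param quiet Suppress stage logging to stderr.
#' @return A list of class `pola_pipeline` with elements `gene_calls`,
#'   `screen`, `classification`, `families`, `profiles`, `predictions`,
#'   `prevalence`, `clusters`, `tree`, `concat_msa`, `concat_tree`, `clades`,
#'   `abundance`, `assignments`, `core`, `config`, `counts`.
#' @export
run_pipeline <- function(contigs, reads = NULL, config = pipeline_config(),
                         panel = marker_panel(), anchors = anchor_panel(),
                         gene_calls = NULL, clade_references = NULL,
                         compute_core = FALSE, out_dir = NULL, quiet = FALSE) {
  t0 <- Sys.time()
  if (is.null(gene_calls)) {
    if (is.null(contigs) || nrow(contigs) == 0L) {
      abort("Stage gene_calling: no contigs supplied.")
    }
    gene_calls <- find_orfs_all(contigs, min_len_aa = config$min_orf_len, longest_only = TRUE)
  }
  if (nrow(gene_calls) == 0L) abort("Stage gene_calling: no ORFs found in the input contigs.")
  peptides <- gene_calls |>
    transmute(id = .data$peptide_id, sequence = .data$peptide, contig_id = .data$contig_id)
  stage_log(quiet, "gene_calling: %d contigs -> %d peptides", length(unique(gene_calls$contig_id)), nrow(peptides))

  scores <- panel_scores(peptides, panel)
  screen <- screen_pola(peptides, panel,
    e_cutoff = config$e_cutoff_screen,
    min_len = config$min_len, scores = scores
  )
  if (nrow(screen) == 0L) abort("Stage screen: no PolA candidates passed the screen.")
  stage_log(quiet, "screen: %d PolA candidates", nrow(screen))

  pola_maps <- anchor_maps(screen, anchors$pola)
  classification <- classify_762(screen, anchors$pola, maps = pola_maps)
  stage_log(quiet, "classify_762: %s", paste(
    utils::capture.output(print(table(classification$pol_type)))[2],
    collapse = " "
  ))

  families <- assign_family(peptides, panel,
    e_cutoff = config$e_cutoff_screen, scores = scores
  )
  profiles <- profile_contigs(
    gene_calls |> semi_join(screen |> inner_join(peptides, by = c("id", "sequence")), by = "contig_id"),
    families, classification
  )
  predictions <- field_guide_predict(profiles)
  profiles$group <- predictions$predicted_group
  prevalence <- group_gene_prevalence(profiles)
  stage_log(quiet, "profiles: %d PolA contigs", nrow(profiles))

  # 75% AAI clustering of screened PolA peptides over the partial window
  msa <- stack_anchored_alignment(screen, anchors$pola, "partial",
    min_coverage = config$window_coverage, maps = pola_maps
  )
  clusters <- NULL
  tree <- NULL
  if (nrow(msa) >= 2L) {
    dm <- identity_distance_matrix(msa)
    clusters <- furthest_neighbor_clusters(dm, 1 - config$aai_cutoff, peptides = screen)
    reps <- clusters$id[clusters$representative]
    if (length(reps) >= 3L) {
      tree <- bootstrap_support(
        msa[reps, , drop = FALSE],
        n_reps = config$bootstrap_reps, seed = config$seed
      )
    }
    stage_log(quiet, "clustering: %d clusters at %.0f%% AAI", max(clusters$cluster), 100 * config$aai_cutoff)
  }

  concat <- concat_clade_stage(
    profiles, peptides, families, anchors, config, clade_references, quiet
  )

  abundance <- NULL
  assignments <- NULL
  if (!is.null(reads) && nrow(reads) > 0L) {
    if (all(c("read_id", "contig_id") %in% names(reads))) {
      assignments <- reads
    } else {
      assignments <- recruit_reads_exact(reads, contigs)
    }
    abundance <- combination_abundance(profiles, assignments)
    stage_log(quiet, "abundance: %d uniquely recruited reads", sum(!is.na(assignments$contig_id)))
  }

  core <- NULL
  if (compute_core && !is.null(concat$clades)) {
    pr_contigs <- concat$clades$contig_id[!is.na(concat$clades$clade)]
    pep_sub <- peptides |> filter(.data$contig_id %in% pr_contigs)
    if (nrow(pep_sub) > 0L) {
      hg <- homology_graph_clusters(pep_sub, e_cutoff = config$e_cutoff_graph)
      core <- core_clusters(
        hg, pep_sub |> select("id", "contig_id"),
        concat$clades |> filter(!is.na(.data$clade)) |> select("contig_id", "clade"),
        fraction = config$core_fraction
      )
      stage_log(quiet, "core: %d core clusters", sum(core$core))
    }
  }

  out <- structure(
    list(
      gene_calls = gene_calls, screen = screen, classification = classification,
      families = families, profiles = profiles, predictions = predictions,
      prevalence = prevalence, clusters = clusters, tree = tree,
      concat_msa = concat$msa, concat_tree = concat$tree, clades = concat$clades,
      abundance = abundance, assignments = assignments, core = core,
      config = config,
      counts = tibble(
        stage = c("contigs", "peptides", "pola_screened", "pola_contigs", "clusters"),
        n = c(
          length(unique(gene_calls$contig_id)), nrow(peptides), nrow(screen),
          nrow(profiles), if (is.null(clusters)) 0L else max(clusters$cluster)
        )
      ),
      elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "pola_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

# Concatenated PolA+RNR stage: anchored regions, NJ tree, clade resolution.
concat_clade_stage <- function(profiles, peptides, families, anchors, config,
                               clade_references, quiet) {
  with_rnr <- profiles |> filter(!is.na(.data$rnr_class))
  if (nrow(with_rnr) < 3L) {
    return(list(msa = NULL, tree = NULL, clades = if (nrow(with_rnr)) {
      resolve_clades(with_rnr |> select("contig_id", "rnr_class", "pol_type"))
    } else {
      NULL
    }))
  }
  rnr_peps <- peptides |>
    inner_join(families, by = c(id = "peptide_id")) |>
    filter(.data$contig_id %in% with_rnr$contig_id, .data$family %in% RNR_LABELS) |>
    group_by(.data$contig_id) |>
    arrange(desc(.data$score), .data$id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  pola_in <- with_rnr |>
    inner_join(peptides |> select("id", "sequence"), by = c(peptide_id = "id")) |>
    transmute(id = .data$contig_id, sequence = .data$sequence)
  rnr_in <- rnr_peps |> transmute(id = .data$contig_id, sequence = .data$sequence)
  if (!is.null(clade_references)) {
    pola_in <- bind_rows(pola_in, clade_references |> transmute(id = .data$id, sequence = .data$pola_sequence))
    rnr_in <- bind_rows(rnr_in, clade_references |> transmute(id = .data$id, sequence = .data$rnr_sequence))
  }
  pola_msa <- stack_anchored_alignment(pola_in, anchors$pola, "concat",
    min_coverage = config$window_coverage
  )
  rnr_msa <- stack_anchored_alignment(rnr_in, anchors$nrda, "rnr_region",
    min_coverage = config$window_coverage
  )
  cmsa <- concatenate_markers(pola_msa, rnr_msa)
  ctree <- if (nrow(cmsa) >= 3L) {
    bootstrap_support(cmsa, n_reps = config$bootstrap_reps, seed = config$seed)
  } else {
    NULL
  }
  labels <- if (!is.null(clade_references)) {
    clade_references |> transmute(contig_id = .data$id, clade = .data$clade)
  } else {
    NULL
  }
  clades <- resolve_clades(
    with_rnr |> select("contig_id", "rnr_class", "pol_type"),
    tree = ctree, labels = labels
  )
  stage_log(quiet, "clades: %d/%d resolved", sum(!is.na(clades$clade)), nrow(clades))
  list(msa = cmsa, tree = ctree, clades = clades)
}

# Serialize every pipeline artifact under `dir`.
write_pipeline <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) if (!is.null(x)) write_tsv_table(x, file.path(dir, name))
  w(result$gene_calls |> select(-"peptide"), "gene_calls.tsv")
  w(result$screen |> select(-"sequence"), "pola_screen.tsv")
  w(result$classification, "classification.tsv")
  w(result$families, "families.tsv")
  if (!is.null(result$profiles)) {
    w(
      result$profiles |>
        mutate(
          helicases = purrr::map_chr(.data$helicases, paste, collapse = ","),
          accessory = purrr::map_chr(.data$accessory, paste, collapse = ",")
        ) |>
        select(-"gene_order"),
      "profiles.tsv"
    )
  }
  if (!is.null(result$predictions)) {
    w(
      result$predictions |>
        mutate(clade_candidates = purrr::map_chr(.data$clade_candidates, paste, collapse = ",")),
      "field_guide.tsv"
    )
  }
  w(result$prevalence, "prevalence.tsv")
  w(result$clusters, "clusters.tsv")
  if (!is.null(result$clades)) {
    w(
      result$clades |>
        mutate(candidates = purrr::map_chr(.data$candidates, paste, collapse = ",")),
      "clades.tsv"
    )
  }
  w(result$abundance, "abundance.tsv")
  w(result$assignments, "read_assignments.tsv")
  w(result$core, "core_clusters.tsv")
  w(result$counts, "stage_counts.tsv")
  if (!is.null(result$tree)) write_newick(result$tree, file.path(dir, "pola_partial_tree.nwk"))
  if (!is.null(result$concat_tree)) write_newick(result$concat_tree, file.path(dir, "concat_tree.nwk"))
  invisible(dir)
}

#' @export
print.pola_pipeline <- function(x, ...) {
  cat("<pola_pipeline>\n")
  print(x$counts)
  invisible(x)
}

#' Tidy per-contig pipeline summary
#'
#' One row per PolA-bearing contig: 762 type, field-guide group and
#' lifestyle, replisome combination, RNR class and resolved clade.
#'
#' @param x A `pola_pipeline` result.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.pola_pipeline <- function(x, ...) {
  out <- x$profiles |>
    select("contig_id", "residue762", "pol_type", "group", "rnr_class", "combination") |>
    left_join(
      x$predictions |> select("contig_id", "lifestyle", "rule_trace", "conflicts"),
      by = "contig_id"
    )
  if (!is.null(x$clades)) {
    out <- out |> left_join(x$clades |> select("contig_id", "clade", "resolution"), by = "contig_id")
  }
  out
}

#' One-row pipeline summary
#'
#' @param x A `pola_pipeline` result.
#' @param ... Unused.
#' @return A one-row tibble of stage counts and elapsed seconds.
#' @exportS3Method generics::glance
glance.pola_pipeline <- function(x, ...) {
  tibble(
    n_contigs = x$counts$n[x$counts$stage == "contigs"],
    n_peptides = x$counts$n[x$counts$stage == "peptides"],
    n_pola = x$counts$n[x$counts$stage == "pola_screened"],
    n_pola_contigs = x$counts$n[x$counts$stage == "pola_contigs"],
    n_clusters = x$counts$n[x$counts$stage == "clusters"],
    n_clades_resolved = if (is.null(x$clades)) 0L else sum(!is.na(x$clades$clade)),
    elapsed_s = x$elapsed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot gene prevalence per group
#'
#' Bar chart of the percentage of contigs carrying each gene, faceted by
#' group.
#'
#' @param object A `pola_prevalence` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pola_prevalence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$percent,
    y = stats::reorder(.data$gene, .data$percent)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group), scales = "free_y") +
    ggplot2::labs(
      x = "% of contigs in group", y = NULL,
      title = "Replisome gene prevalence by PolA group"
    )
}

#' Plot combination read-mass shares
#'
#' @param object A `pola_abundance` tibble.
#' @param top Show the `top` most abundant combinations (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pola_abundance <- function(object, top = 10, ...) {
  df <- utils::head(object[order(-object$fraction), ], top)
  df$label <- paste(df$group, df$combination, sep = " / ")
  ggplot2::ggplot(df, ggplot2::aes(
    x = 100 * .data$fraction,
    y = stats::reorder(.data$label, .data$fraction)
  )) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "% of recruited reads", y = NULL,
      title = "Read mass by PolA + replication-gene combination"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
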