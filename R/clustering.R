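#' Pairwise amino-acid identity distances over anchored columns
#'
#' Computes `1 - identity` between every pair of rows of an anchored
#' alignment ([stack_anchored_alignment()]). Identity counts matching residues
#' over columns where at least one of the pair has a residue, excluding
#' columns that fall in either sequence's *terminal* gap runs (positions
#' before its first or after its last residue). Rows with zero window
#' coverage are excluded with a warning. Pairs sharing no countable column
#' get distance 1.
#'
#' @param msa A character matrix (rows = peptides, columns = anchored
#'   positions, `-` = gap) with rownames, e.g. from
#'   [stack_anchored_alignment()].
#' @return A list of class `pep_dist` with elements `ids` and `d` (symmetric
#'   matrix, zero diagonal).
#' @export
identity_distance_matrix <- function(msa) {
  stopifnot(is.matrix(msa), !is.null(rownames(msa)))
  nongap <- msa != "-"
  cov <- rowSums(nongap)
  if (any(cov == 0L)) {
    warn(sprintf(
      "Excluding %d peptide(s) with zero window coverage: %s",
      sum(cov == 0L), paste(rownames(msa)[cov == 0L], collapse = ", ")
    ))
    msa <- msa[cov > 0L, , drop = FALSE]
    nongap <- nongap[cov > 0L, , drop = FALSE]
  }
  n <- nrow(msa)
  if (n < 2L) abort("Need at least two peptides with non-zero coverage.")
  # matches: columns where both residues present and equal
  letters_used <- setdiff(unique(as.vector(msa)), "-")
  M <- matrix(0, n, n)
  for (a in letters_used) {
    ind <- (msa == a) * 1
    M <- M + tcrossprod(ind)
  }
  # span indicator: columns between each row's first and last residue
  span <- matrix(0, n, ncol(msa))
  for (i in seq_len(n)) {
    w <- which(nongap[i, ])
    span[i, w[1]:w[length(w)]] <- 1
  }
  NG <- nongap * 1
  B <- tcrossprod(NG) # both non-gap
  NS <- tcrossprod(NG, span) # i non-gap within j's span
  D <- NS + t(NS) - B
  identity <- ifelse(D > 0, M / D, 0)
  d <- 1 - identity
  diag(d) <- 0
  dimnames(d) <- list(rownames(msa), rownames(msa))
  structure(list(ids = rownames(msa), d = d), class = "pep_dist")
}

#' Furthest-neighbour (complete-linkage) clustering at a distance cutoff
#'
#' Agglomerative complete-linkage clustering in which two clusters merge only
#' while the merged cluster's maximum pairwise distance stays at or below
#' `cutoff` (the Mothur "furthest neighbor" convention: identity >= 75%
#' corresponds to `cutoff = 0.25`). Every output cluster therefore satisfies
#' the diameter invariant `max intra-cluster distance <= cutoff`.
#'
#' @param dist_obj A `pep_dist` (see [identity_distance_matrix()]) or a
#'   symmetric numeric matrix with dimnames.
#' @param cutoff Distance threshold in `[0, 1]`.
#' @param peptides Optional data frame (`id`, `sequence`) used to pick a
#'   representative per cluster: longest member, ties broken by
#'   lexicographically smallest id.
#' @return A tibble `cluster` (integer), `id`, `representative` (logical),
#'   with attribute `cutoff`. Clusters are numbered by first appearance of
#'   their lexicographically smallest member.
#' @export
furthest_neighbor_clusters <- function(dist_obj, cutoff = 0.25, peptides = NULL) {
  if (cutoff < 0 || cutoff > 1) abort("`cutoff` must be in [0, 1].")
  d <- if (inherits(dist_obj, "pep_dist")) dist_obj$d else as.matrix(dist_obj)
  ids <- rownames(d)
  stopifnot(!is.null(ids))
  n <- nrow(d)
  if (n == 1L) {
    membership <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    membership <- stats::cutree(hc, h = cutoff + 1e-12)
  }
  out <- tibble(id = ids, cluster_raw = unname(membership[ids]))
  relabel <- out |>
    group_by(.data$cluster_raw) |>
    summarise(first_id = min(.data$id), .groups = "drop") |>
    arrange(.data$first_id) |>
    mutate(cluster = row_number())
  out <- out |>
    left_join(relabel |> select("cluster_raw", "cluster"), by = "cluster_raw") |>
    select("cluster", "id") |>
    arrange(.data$cluster, .data$id)
  out$representative <- FALSE
  if (!is.null(peptides)) {
    lens <- stats::setNames(nchar(peptides$sequence), peptides$id)
    reps <- out |>
      mutate(len = unname(lens[.data$id])) |>
      group_by(.data$cluster) |>
      arrange(desc(.data$len), .data$id, .by_group = TRUE) |>
      slice(1) |>
      ungroup()
    out$representative <- paste(out$cluster, out$id) %in% paste(reps$cluster, reps$id)
  }
  attr(out, "cutoff") <- cutoff
  out
}

#' Maximum intra-cluster distance per cluster
#'
#' Diagnostic companion to [furthest_neighbor_clusters()]: for each cluster,
#' the largest pairwise distance among members (0 for singletons).
#'
#' @param clusters Tibble from [furthest_neighbor_clusters()].
#' @param dist_obj The distance object the clustering was built from.
#' @return A tibble `cluster`, `diameter`.
#' @export
cluster_diameters <- function(clusters, dist_obj) {
  d <- if (inherits(dist_obj, "pep_dist")) dist_obj$d else as.matrix(dist_obj)
  clusters |>
    group_by(.data$cluster) |>
    summarise(
      diameter = if (n() < 2) 0 else max(d[.data$id, .data$id]),
      .groups = "drop"
    )
}

#' Cross-library overlap of clusters
#'
#' Counts clusters whose members come only from source `a`, only from source
#' `b`, or from both. Only clusters containing at least one member from `a`
#' or `b` enter the total.
#'
#' @param clusters Tibble with columns `cluster`, `id`.
#' @param sources Named character vector or data frame (`id`, `source`)
#'   mapping every member id to a source label.
#' @param source_a,source_b The two source labels to compare.
#' @return A one-row tibble: `shared`, `a_only`, `b_only`, `total`
#'   (`shared + a_only + b_only == total`).
#' @export
source_overlap <- function(clusters, sources, source_a, source_b) {
  if (is.data.frame(sources)) {
    sources <- stats::setNames(sources$source, sources$id)
  }
  unmapped <- setdiff(clusters$id, names(sources))
  if (length(unmapped) > 0L) {
    abort(sprintf("No source mapped for id(s): %s", paste(utils::head(unmapped, 3), collapse = ", ")))
  }
  per <- clusters |>
    mutate(source = unname(sources[.data$id])) |>
    group_by(.data$cluster) |>
    summarise(
      has_a = any(.data$source == source_a),
      has_b = any(.data$source == source_b),
      .groups = "drop"
    ) |>
    filter(.data$has_a | .data$has_b)
  tibble(
    shared = sum(per$has_a & per$has_b),
    a_only = sum(per$has_a & !per$has_b),
    b_only = sum(per$has_b & !per$has_a),
    total = nrow(per)
  )
}

#' Single-linkage clustering on a homology hit graph
#'
#' Builds an undirected graph with one node per peptide and an edge whenever
#' either direction of the all-vs-all local-alignment search passes the
#' E-value cutoff, then reports connected components (the "cluster on your
#' hits" convention of all-vs-all protein searches).
#'
#' @param peptides Data frame with columns `id`, `sequence`. Ignored when a
#'   precomputed `hits` table is supplied (only `id` is used then).
#' @param e_cutoff E-value cutoff for an edge (default `1e-20`).
#' @param params [align_params()].
#' @param hits Optional precomputed hit table with columns `query`, `subject`,
#'   `e_value` (self-hits ignored). When absent, all-vs-all local alignments
#'   are computed.
#' @return A tibble `cluster`, `id` (clusters numbered by smallest member id).
#' @export
homology_graph_clusters <- function(peptides, e_cutoff = 1e-20,
                                    params = align_params(), hits = NULL) {
  ids <- peptides$id
  if (length(ids) == 0L) abort("Need at least one peptide.")
  if (is.null(hits)) hits <- all_vs_all_hits(peptides, params)
  hits <- hits[hits$query != hits$subject & hits$e_value <= e_cutoff, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    hits[, c("query", "subject")],
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)$membership
  out <- tibble(id = names(comp), cluster_raw = unname(comp))
  relabel <- out |>
    group_by(.data$cluster_raw) |>
    summarise(first_id = min(.data$id), .groups = "drop") |>
    arrange(.data$first_id) |>
    mutate(cluster = row_number())
  out |>
    left_join(relabel |> select("cluster_raw", "cluster"), by = "cluster_raw") |>
    select("cluster", "id") |>
    arrange(.data$cluster, .data$id)
}

# All-vs-all local alignment hits (upper triangle; scores are symmetric).
all_vs_all_hits <- function(peptides, params = align_params()) {
  n <- nrow(peptides)
  total_res <- sum(nchar(peptides$sequence))
  rows <- list()
  for (j in seq_len(n)) {
    if (j == n) break
    qidx <- (j + 1L):n
    sc <- local_scores(peptides$sequence[qidx], peptides$sequence[j], params)
    ev <- karlin_altschul_evalue(sc, nchar(peptides$sequence[qidx]), total_res, params)
    rows[[j]] <- tibble(
      query = peptides$id[qidx], subject = peptides$id[j],
      score = sc, e_value = ev
    )
  }
  if (length(rows) == 0L) {
    return(tibble(query = character(), subject = character(), score = numeric(), e_value = numeric()))
  }
  list_rbind(rows)
}

#' Per-clade core clusters
#'
#' A cluster is *core* for a clade when it has at least one member on at
#' least `ceiling(fraction * n_contigs(clade))` of the clade's contigs.
#'
#' @param clusters Tibble `cluster`, `id` (peptide ids).
#' @param membership Data frame mapping `id` (peptide) to `contig_id`.
#' @param clades Data frame mapping `contig_id` to `clade`; contigs may be
#'   assigned to at most one clade. Clades with zero contigs are dropped with
#'   a warning.
#' @param fraction Core threshold (default 0.5).
#' @return A tibble `clade`, `cluster`, `n_contigs` (contigs of the clade
#'   carrying the cluster), `clade_size`, `core` (logical).
#' @export
core_clusters <- function(clusters, membership, clades, fraction = 0.5) {
  stopifnot(all(c("id", "contig_id") %in% names(membership)))
  stopifnot(all(c("contig_id", "clade") %in% names(clades)))
  if (anyDuplicated(clades$contig_id) > 0L) {
    abort("Each contig may be assigned to at most one clade.")
  }
  clade_sizes <- clades |> count(.data$clade, name = "clade_size")
  empty <- clade_sizes$clade[clade_sizes$clade_size == 0L]
  if (length(empty) > 0L) warn(sprintf("Dropping empty clade(s): %s", paste(empty, collapse = ", ")))
  hits <- clusters |>
    inner_join(membership, by = "id") |>
    inner_join(clades, by = "contig_id") |>
    distinct(.data$clade, .data$cluster, .data$contig_id) |>
    count(.data$clade, .data$cluster, name = "n_contigs") |>
    left_join(clade_sizes, by = "clade") |>
    mutate(core = .data$n_contigs >= ceiling(fraction * .data$clade_size)) |>
    arrange(.data$clade, desc(.data$core), .data$cluster)
  hits
}
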