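#' Stack peptides into a reference-anchored alignment
#'
#' Each peptide is aligned to the anchor once (ends-free global alignment);
#' column `j` of the result holds the query residue mapped to reference
#' position `window_start + j - 1`, or `-` when that position is deleted in
#' the query. Insertions relative to the reference are discarded, which fixes
#' column homology without a multiple-alignment heuristic. Peptides mapping
#' fewer than `min_coverage` of the window positions are dropped (attribute
#' `dropped` lists them).
#'
#' @param peptides Data frame with columns `id`, `sequence`.
#' @param anchor A [reference_anchor()].
#' @param window Window label on the anchor.
#' @param min_coverage Minimum fraction of window positions mapped
#'   (default 0.8).
#' @param params [align_params()].
#' @param maps Optional precomputed anchor maps (internal use).
#' @return A character matrix (rows = peptide ids, cols = window positions)
#'   with attributes `window`, `anchor`, `coverage` (named numeric) and
#'   `dropped`.
#' @export
stack_anchored_alignment <- function(peptides, anchor, window, min_coverage = 0.8,
                                     params = align_params(), maps = NULL) {
  if (nrow(peptides) == 0L) abort("No peptides to stack.")
  w <- anchor$windows[[window]]
  if (is.null(w)) abort(sprintf("Anchor '%s' has no window '%s'.", anchor$name, window))
  if (is.null(maps)) maps <- anchor_maps(peptides, anchor, params)
  cols <- w[1]:w[2]
  rows <- matrix("-", nrow(peptides), length(cols),
    dimnames = list(peptides$id, NULL)
  )
  coverage <- numeric(nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    m <- maps[[peptides$id[i]]][cols]
    ok <- !is.na(m)
    coverage[i] <- mean(ok)
    if (any(ok)) {
      chars <- seq_chars(peptides$sequence[i])
      rows[i, ok] <- chars[m[ok]]
    }
  }
  names(coverage) <- peptides$id
  keep <- coverage >= min_coverage
  out <- rows[keep, , drop = FALSE]
  attr(out, "window") <- window
  attr(out, "anchor") <- anchor$name
  attr(out, "coverage") <- coverage[keep]
  attr(out, "dropped") <- peptides$id[!keep]
  out
}

#' Uncorrected p-distances over an anchored alignment
#'
#' Pairwise mismatch fraction over columns where both rows carry residues.
#' Pairs sharing no column are an error (they carry no signal for tree
#' building).
#'
#' @param msa Character matrix with rownames (rows = taxa).
#' @return A `pep_dist` list (`ids`, `d`).
#' @export
p_distance <- function(msa) {
  stopifnot(is.matrix(msa), !is.null(rownames(msa)))
  n <- nrow(msa)
  if (n < 2L) abort("Need at least two rows.")
  nongap <- (msa != "-") * 1
  B <- tcrossprod(nongap)
  letters_used <- setdiff(unique(as.vector(msa)), "-")
  M <- matrix(0, n, n)
  for (a in letters_used) {
    ind <- (msa == a) * 1
    M <- M + tcrossprod(ind)
  }
  off <- B == 0 & row(B) != col(B)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Rows '%s' and '%s' share no aligned columns.",
      rownames(msa)[bad[1]], rownames(msa)[bad[2]]
    ))
  }
  d <- 1 - M / B
  diag(d) <- 0
  dimnames(d) <- list(rownames(msa), rownames(msa))
  structure(list(ids = rownames(msa), d = d), class = "pep_dist")
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining on a distance matrix, with negative branch
#' lengths clamped to zero. Deterministic for a fixed input.
#'
#' @param dist_obj A `pep_dist` or symmetric numeric matrix with dimnames
#'   (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dist_obj) {
  d <- if (inherits(dist_obj, "pep_dist")) dist_obj$d else as.matrix(dist_obj)
  if (nrow(d) < 3L) abort("Neighbour joining needs at least 3 taxa.")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for an anchored-alignment tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `build_fn`, and reports for each internal edge of the
#' full-data tree the fraction of replicate trees containing the same
#' bipartition (stored in `node.label`).
#'
#' @param msa Character matrix with rownames.
#' @param build_fn Function `msa -> phylo` (default: p-distance + NJ).
#' @param n_reps Number of replicates (>= 1; the headline trees here use 10).
#' @param seed Seed for the column resampling.
#' @return The full-data `phylo` with `node.label` = support fractions
#'   (`NA` on the root node).
#' @export
bootstrap_support <- function(msa, build_fn = NULL, n_reps = 10, seed = 1) {
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  if (is.null(build_fn)) build_fn <- function(m) neighbor_joining(p_distance(m))
  tree <- build_fn(msa)
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(i) {
      cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
      build_fn(msa[, cols, drop = FALSE])
    })
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- counts / n_reps
  tree$node.label <- as.character(support)
  attr(tree, "support") <- support
  tree
}

#' Concatenate anchored PolA and RNR regions per contig
#'
#' Joins the PolA `concat` window (143 columns) and the RNR `rnr_region`
#' window (189 columns) for contigs carrying both markers -- PolA block
#' first, 332 columns when both windows are fully covered. Contigs missing
#' either marker are excluded and listed in attribute `excluded`.
#'
#' @param pola_msa,rnr_msa Anchored matrices whose rownames are contig ids.
#' @return A character matrix with attribute `excluded`.
#' @export
concatenate_markers <- function(pola_msa, rnr_msa) {
  shared <- intersect(rownames(pola_msa), rownames(rnr_msa))
  excluded <- setdiff(union(rownames(pola_msa), rownames(rnr_msa)), shared)
  if (length(shared) == 0L) abort("No contig carries both markers.")
  out <- cbind(pola_msa[shared, , drop = FALSE], rnr_msa[shared, , drop = FALSE])
  attr(out, "excluded") <- excluded
  out
}

CLADE_MAP <- list(
  "RNR-I-Other|Tyr762" = c(2L, 3L),
  "RNR-I-Other|Phe762" = 4L,
  "RNR-I-CyanoSP|Tyr762" = 5L,
  "RNR-II-RTPR|Tyr762" = 6L,
  "RNR-II-RTPR|Phe762" = 7L,
  "RNR-II-Other|Tyr762" = c(1L, 8L),
  "RNR-II-Other|Phe762" = c(1L, 9L),
  "RNR-II-Other|Leu762" = 1L
)

#' Candidate clades for an (RNR class, PolA type) combination
#'
#' The nine concatenated-tree clades are delineated by the combination of
#' RNR class and PolA 762-type: clades 1/8/9 carry Class II Other RNR, 2/3/4
#' Class I Other, 5 Class I Cyano SP, 6/7 Class II RTPR; within each RNR
#' block the 762-type splits the clades, and clade 1 is the only mixed-type
#' clade. Combinations absent from the map yield an empty candidate set.
#'
#' @param rnr_class Character vector over
#'   `RNR-I-Other`/`RNR-I-CyanoSP`/`RNR-II-Other`/`RNR-II-RTPR` (NA = no RNR).
#' @param pol_type Character vector over
#'   `Phe762`/`Tyr762`/`Leu762`/`Other`/`Unresolved`.
#' @return A list of integer candidate vectors (possibly empty).
#' @export
assign_clade <- function(rnr_class, pol_type) {
  stopifnot(length(rnr_class) == length(pol_type))
  ok_rnr <- is.na(rnr_class) | rnr_class %in% RNR_LABELS
  ok_pol <- pol_type %in% c("Phe762", "Tyr762", "Leu762", "Other", "Unresolved")
  if (!all(ok_rnr)) abort(sprintf("Unknown RNR class label: %s", rnr_class[!ok_rnr][1]))
  if (!all(ok_pol)) abort(sprintf("Unknown PolA type label: %s", pol_type[!ok_pol][1]))
  purrr::map2(rnr_class, pol_type, function(r, p) {
    if (is.na(r)) return(integer())
    CLADE_MAP[[paste(r, p, sep = "|")]] %||% integer()
  })
}

#' Resolve clade assignments, optionally by tree placement
#'
#' Single-candidate combinations resolve directly. Multi-candidate
#' combinations (clades 2/3 and the Class II Other set 1/8/9) are resolved by
#' the nearest labelled leaf on the concatenated tree whose known clade lies
#' in the candidate set (patristic distance; ties broken by label order);
#' without a tree or labelled references the candidate set is reported
#' unresolved.
#'
#' @param assignments Tibble with columns `contig_id`, `rnr_class`,
#'   `pol_type`.
#' @param tree Optional `phylo` whose tips include the contig ids and the
#'   labelled reference leaves.
#' @param labels Optional data frame `contig_id`, `clade` for labelled
#'   reference leaves on `tree`.
#' @return A tibble `contig_id`, `rnr_class`, `pol_type`, `candidates`
#'   (list column), `clade` (integer, NA when unresolved), `resolution`
#'   (`"unique"`, `"tree"`, `"candidate_set"`, or `"unassigned"`).
#' @export
resolve_clades <- function(assignments, tree = NULL, labels = NULL) {
  cand <- assign_clade(assignments$rnr_class, assignments$pol_type)
  out <- assignments |>
    mutate(candidates = cand, clade = NA_integer_, resolution = "unassigned")
  n_cand <- lengths(cand)
  out$resolution[n_cand == 1L] <- "unique"
  out$clade[n_cand == 1L] <- unlist(cand[n_cand == 1L])
  multi <- which(n_cand > 1L)
  if (length(multi) > 0L) {
    if (!is.null(tree) && !is.null(labels) && nrow(labels) > 0L) {
      dmat <- stats::cophenetic(tree)
      for (i in multi) {
        cid <- out$contig_id[i]
        refs <- labels[labels$clade %in% out$candidates[[i]] & labels$contig_id %in% rownames(dmat), , drop = FALSE]
        if (cid %in% rownames(dmat) && nrow(refs) > 0L) {
          dd <- dmat[cid, refs$contig_id]
          pick <- refs$clade[order(dd, refs$contig_id)][1]
          out$clade[i] <- pick
          out$resolution[i] <- "tree"
        } else {
          out$resolution[i] <- "candidate_set"
        }
      }
    } else {
      out$resolution[multi] <- "candidate_set"
    }
  }
  out
}

#' Write / read Newick trees
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; support
#' values (if any) travel as internal node labels.
#'
#' @param tree A `phylo`.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
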