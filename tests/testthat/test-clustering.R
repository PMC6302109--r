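toy_msa <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  m
}

test_that("anchored identity distances match direct residue counting", {
  m <- toy_msa(c(a = "AAAA", b = "AAAT"))
  d <- identity_distance_matrix(m)
  expect_equal(d$d["a", "b"], 0.25)
  expect_equal(d$d["a", "a"], 0)

  m2 <- toy_msa(c(a = "MKLVA", b = "MKLVA"))
  expect_equal(identity_distance_matrix(m2)$d["a", "b"], 0)

  # random gapped instances vs the independent recount oracle
  set.seed(12)
  aa <- c("A", "C", "D", "E", "-")
  for (rep in 1:10) {
    rows <- replicate(4, paste(sample(aa, 20, replace = TRUE, prob = c(rep(0.2, 4), 0.2)), collapse = ""))
    rows[1] <- gsub("-", "A", rows[1]) # keep at least one full row
    names(rows) <- paste0("s", 1:4)
    m <- toy_msa(rows)
    keep <- rowSums(m != "-") > 0
    m <- m[keep, , drop = FALSE]
    d <- suppressWarnings(identity_distance_matrix(m))
    for (i in seq_len(nrow(m) - 1)) {
      for (j in (i + 1):nrow(m)) {
        expect_equal(
          d$d[i, j], 1 - recount_identity(m[i, ], m[j, ]),
          info = sprintf("rep %d pair %d-%d", rep, i, j)
        )
      }
    }
  }
})

test_that("terminal gaps are excluded from the identity denominator", {
  # b covers only columns 3..6; within that overlap a and b agree at 3 of 4
  m <- toy_msa(c(a = "MKLVAC", b = "--LVAW"))
  d <- identity_distance_matrix(m)
  expect_equal(d$d["a", "b"], 1 - 3 / 4)
})

test_that("furthest-neighbour clustering obeys the diameter rule", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.4
  d["B", "C"] <- d["C", "B"] <- 0.4
  cl <- furthest_neighbor_clusters(d, 0.25)
  grp <- split(cl$id, cl$cluster)
  expect_equal(length(grp), 2)
  expect_true(any(vapply(grp, function(g) setequal(g, c("A", "B")), TRUE)))

  # exhaustive check: of all partitions of {A,B,C} respecting the diameter
  # rule, {A,B},{C} is the unique coarsest one
  expect_true(max(d[c("A", "B"), c("A", "B")]) <= 0.25)
  expect_false(max(d) <= 0.25)

  # all-zero distances collapse to one cluster; cutoff 0 with distinct
  # sequences leaves singletons
  dz <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_equal(max(furthest_neighbor_clusters(dz, 0.25)$cluster), 1)
  expect_equal(max(furthest_neighbor_clusters(d, 0)$cluster), 3)
  expect_error(furthest_neighbor_clusters(d, 1.5), "cutoff")
})

test_that("cluster diameters never exceed the cutoff (property over random matrices)", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    for (cutoff in c(0, 0.1, 0.25, 0.5)) {
      cl <- furthest_neighbor_clusters(d, cutoff)
      expect_true(all(cluster_diameters(cl, d)$diameter <= cutoff + 1e-12))
    }
    # cluster count is non-increasing in the cutoff
    counts <- vapply(
      c(0, 0.1, 0.25, 0.5),
      function(h) max(furthest_neighbor_clusters(d, h)$cluster), 1
    )
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("representatives are the longest member with lexicographic ties", {
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "long"), c("a", "b", "long")))
  peps <- tibble::tibble(
    id = c("a", "b", "long"),
    sequence = c(strrep("A", 200), strrep("A", 200), strrep("A", 300))
  )
  cl <- furthest_neighbor_clusters(d, 0.25, peptides = peps)
  expect_equal(cl$id[cl$representative], "long")
  # drop the long one: equal lengths, 'a' wins on id order
  cl2 <- furthest_neighbor_clusters(d[1:2, 1:2], 0.25, peptides = peps[1:2, ])
  expect_equal(cl2$id[cl2$representative], "a")
  # a singleton represents itself
  cl3 <- furthest_neighbor_clusters(d[1, 1, drop = FALSE], 0.25, peptides = peps[1, ])
  expect_equal(cl3$id[cl3$representative], "a")
})

test_that("source overlap reproduces the published cluster arithmetic", {
  # 69 shared + 31 a-only + 81 b-only clusters
  clusters <- tibble::tibble(
    cluster = c(
      rep(1:69, each = 2),
      70:100,
      101:181
    ),
    id = c(
      paste0(rep(c("m", "s"), times = 69), rep(1:69, each = 2)),
      paste0("monly", 1:31),
      paste0("sonly", 1:81)
    )
  )
  sources <- stats::setNames(
    c(
      rep(c("MgOl", "SERC"), times = 69),
      rep("MgOl", 31), rep("SERC", 81)
    ),
    clusters$id
  )
  ov <- source_overlap(clusters, sources, "MgOl", "SERC")
  expect_equal(ov$shared, 69)
  expect_equal(ov$a_only, 31)
  expect_equal(ov$b_only, 81)
  expect_equal(ov$total, 181)
  expect_equal(ov$shared + ov$a_only + ov$b_only, ov$total)
  # shared fraction of a-containing clusters: 69 of 100
  expect_equal(ov$shared / (ov$shared + ov$a_only), 0.69)
  expect_error(source_overlap(clusters, sources[-1], "MgOl", "SERC"), "No source")
})

test_that("single-source partitions have zero shared clusters", {
  clusters <- tibble::tibble(cluster = c(1, 1, 2), id = c("x1", "x2", "x3"))
  sources <- c(x1 = "A", x2 = "A", x3 = "B")
  ov <- source_overlap(clusters, sources, "A", "B")
  expect_equal(ov$shared, 0)
  expect_equal(ov$total, 2)
})

test_that("homology-graph clusters equal brute-force connected components", {
  # chained edges merge transitively
  hits <- tibble::tibble(
    query = c("A", "B"), subject = c("B", "C"), e_value = c(1e-30, 1e-30)
  )
  peps <- tibble::tibble(id = c("A", "B", "C"), sequence = rep("M", 3))
  cl <- homology_graph_clusters(peps, hits = hits)
  expect_equal(max(cl$cluster), 1)

  # no edges: all singletons
  cl0 <- homology_graph_clusters(peps, hits = hits[0, ])
  expect_equal(max(cl0$cluster), 3)

  # random 20-node graphs vs BFS oracle
  set.seed(77)
  for (rep in 1:20) {
    ids <- sprintf("n%02d", 1:20)
    n_edges <- sample(5:30, 1)
    edges <- tibble::tibble(
      from = sample(ids, n_edges, replace = TRUE),
      to = sample(ids, n_edges, replace = TRUE)
    )
    edges <- edges[edges$from != edges$to, ]
    hits <- tibble::tibble(query = edges$from, subject = edges$to, e_value = 0)
    cl <- homology_graph_clusters(tibble::tibble(id = ids, sequence = "M"), hits = hits)
    oracle <- bfs_components(ids, edges)
    got <- stats::setNames(cl$cluster[match(ids, cl$id)], ids)
    # same partition: co-membership must agree pairwise
    for (i in 1:19) {
      for (j in (i + 1):20) {
        expect_equal(
          got[[ids[i]]] == got[[ids[j]]],
          oracle[[ids[i]]] == oracle[[ids[j]]]
        )
      }
    }
  }
})

test_that("homology edges from alignment respect the E-value cutoff", {
  tmpl <- family_templates()
  peps <- tibble::tibble(
    id = c("g1", "g2", "r1", "lone"),
    sequence = c(
      mutate_peptide(tmpl[["Gp4-like"]], 0.85, seed = 1),
      mutate_peptide(tmpl[["Gp4-like"]], 0.85, seed = 2),
      mutate_peptide(tmpl[["RNR-II-RTPR"]], 0.85, seed = 3),
      rand_pep(300, seed = 4)
    )
  )
  cl <- homology_graph_clusters(peps, e_cutoff = 1e-20)
  memb <- stats::setNames(cl$cluster, cl$id)
  expect_equal(memb[["g1"]], memb[["g2"]])
  expect_false(memb[["g1"]] == memb[["r1"]])
  expect_false(memb[["lone"]] %in% memb[c("g1", "r1")])
})

test_that("core clusters follow the ceiling(half-the-contigs) rule", {
  clusters <- tibble::tibble(
    cluster = c(1, 1, 2, 3),
    id = c("p1", "p2", "p3", "p4")
  )
  membership <- tibble::tibble(
    id = c("p1", "p2", "p3", "p4"),
    contig_id = c("c1", "c2", "c1", "c5")
  )
  clades <- tibble::tibble(
    contig_id = c("c1", "c2", "c3", "c4", "c5"),
    clade = c(1, 1, 1, 1, 2)
  )
  out <- core_clusters(clusters, membership, clades)
  # cluster 1 on 2 of 4 clade-1 contigs -> core
  expect_true(out$core[out$clade == 1 & out$cluster == 1])
  # cluster 2 on 1 of 4 -> not core
  expect_false(out$core[out$clade == 1 & out$cluster == 2])
  # single-contig clade: everything on it is core
  expect_true(out$core[out$clade == 2 & out$cluster == 3])

  # 1 of 3 contigs is below the threshold
  clades3 <- tibble::tibble(contig_id = c("c1", "c2", "c3"), clade = 1)
  out3 <- core_clusters(
    tibble::tibble(cluster = 1, id = "p1"),
    tibble::tibble(id = "p1", contig_id = "c1"),
    clades3
  )
  expect_false(out3$core[1])
  expect_error(
    core_clusters(clusters, membership, dplyr::bind_rows(clades, clades[1, ])),
    "at most one clade"
  )
})
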