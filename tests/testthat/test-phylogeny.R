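test_that("anchored stacking reproduces the reference window and marks deletions", {
  anchors <- anchor_panel()
  pola <- anchors$pola
  msa <- stack_anchored_alignment(
    tibble::tibble(id = "anchor", sequence = pola$peptide), pola, "partial"
  )
  expect_equal(dim(msa), c(1, 125))
  expect_equal(paste(msa[1, ], collapse = ""), substr(pola$peptide, 675, 799))

  # two identical queries give identical rows
  q <- mutate_peptide(pola$peptide, 0.9, seed = 2)
  msa2 <- stack_anchored_alignment(
    tibble::tibble(id = c("a", "b"), sequence = c(q, q)), pola, "partial"
  )
  expect_equal(msa2["a", ], msa2["b", ])

  # a deletion at reference 700..704 leaves gaps in those columns
  chars <- strsplit(pola$peptide, "")[[1]]
  del <- paste(chars[-(700:704)], collapse = "")
  msa3 <- stack_anchored_alignment(
    tibble::tibble(id = "d", sequence = del), pola, "partial"
  )
  cols <- (700:704) - 675 + 1
  expect_true(all(msa3[1, cols] == "-"))
  expect_true(all(msa3[1, -cols] != "-"))

  # coverage filter drops short fragments
  frag <- substr(pola$peptide, 675, 744) # 70 of 125 positions
  msa4 <- stack_anchored_alignment(
    tibble::tibble(id = c("full", "frag"), sequence = c(pola$peptide, frag)),
    pola, "partial",
    min_coverage = 0.8
  )
  expect_equal(rownames(msa4), "full")
  expect_equal(attr(msa4, "dropped"), "frag")
})

test_that("p-distance counts mismatches over shared columns only", {
  m <- rbind(
    a = strsplit(paste(rep("A", 100), collapse = ""), "")[[1]],
    b = strsplit(paste(c(rep("C", 10), rep("A", 90)), collapse = ""), "")[[1]]
  )
  d <- p_distance(m)
  expect_equal(d$d["a", "b"], 0.10)
  expect_equal(d$d["a", "a"], 0)

  # hand-counted 3-taxon toy
  m3 <- rbind(
    x = c("A", "C", "D", "E", "F"),
    y = c("A", "C", "D", "E", "Y"),
    z = c("A", "-", "D", "K", "Y")
  )
  d3 <- p_distance(m3)
  expect_equal(d3$d["x", "y"], 1 / 5)
  expect_equal(d3$d["x", "z"], 2 / 4) # 4 shared columns, E/K and F/Y differ
  expect_equal(d3$d["y", "z"], 1 / 4)

  m_bad <- rbind(a = c("A", "-"), b = c("-", "C"))
  expect_error(p_distance(m_bad), "share no aligned columns")
})

test_that("neighbour joining exactly recovers additive distances", {
  # hand-built quartet: unrooted ((A,B),(C,D)) with internal edge 1
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, LETTERS[1:4])
  cp <- stats::cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cp, d, tolerance = 1e-9)

  # 3 taxa: unique star with closed-form branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- neighbor_joining(d3)
  cp3 <- stats::cophenetic(tr3)[letters[1:3], letters[1:3]]
  expect_equal(cp3, d3, tolerance = 1e-9)
  expect_error(neighbor_joining(d3[1:2, 1:2]), "at least 3")

  # property: NJ reproduces any additive matrix from a random tree
  set.seed(19)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    src <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    dd <- stats::cophenetic(src)
    tr <- neighbor_joining(dd)
    expect_equal(
      stats::cophenetic(tr)[rownames(dd), colnames(dd)], dd,
      tolerance = 1e-8, info = sprintf("replicate %d (n=%d)", rep, n)
    )
  }
})

test_that("negative NJ branch lengths are clamped to zero", {
  set.seed(4)
  # noisy non-additive matrix can induce negative estimates; clamp guarantees >= 0
  n <- 6
  d <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.1, 1)
  d <- d + t(d)
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports separate a clean two-block alignment and are reproducible", {
  block <- function(ch, n) matrix(ch, nrow = n, ncol = 30)
  m <- rbind(
    cbind(block("A", 2), block("C", 2)),
    cbind(block("W", 2), block("Y", 2))
  )
  m[1, 1] <- "G" # tiny within-pair signal so all four tips are distinct
  m[3, 31] <- "H"
  rownames(m) <- c("a1", "a2", "b1", "b2")
  tr <- bootstrap_support(m, n_reps = 10, seed = 5)
  sup <- as.numeric(tr$node.label)
  # the single internal edge separating {a1,a2} from {b1,b2} is certain
  expect_true(any(sup == 1))
  tr2 <- bootstrap_support(m, n_reps = 10, seed = 5)
  expect_equal(tr$node.label, tr2$node.label)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
  # a single replicate yields only 0/1 supports
  tr1 <- bootstrap_support(m, n_reps = 1, seed = 9)
  expect_true(all(as.numeric(tr1$node.label) %in% c(0, 1)))
})

test_that("newick round trip preserves topology, lengths and supports", {
  set.seed(8)
  tr <- ape::rtree(6)
  tr$node.label <- as.character(round(stats::runif(tr$Nnode), 2))
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  back <- read_newick(tf)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), structure(0L, names = "PH85"), ignore_attr = TRUE)
  expect_equal(
    stats::cophenetic(back)[tr$tip.label, tr$tip.label],
    stats::cophenetic(tr),
    tolerance = 1e-9
  )
  expect_equal(back$node.label, tr$node.label)
})

test_that("marker concatenation is PolA-first with 332 columns and excludes incomplete contigs", {
  anchors <- anchor_panel()
  pola_in <- tibble::tibble(
    id = c("c1", "c2", "c3"),
    sequence = c(
      anchors$pola$peptide,
      mutate_peptide(anchors$pola$peptide, 0.85, seed = 1),
      mutate_peptide(anchors$pola$peptide, 0.85, seed = 2)
    )
  )
  rnr_in <- tibble::tibble(
    id = c("c1", "c2"), # c3 lacks an RNR
    sequence = c(
      anchors$nrda$peptide,
      mutate_peptide(anchors$nrda$peptide, 0.85, seed = 3)
    )
  )
  pm <- stack_anchored_alignment(pola_in, anchors$pola, "concat")
  rm_ <- stack_anchored_alignment(rnr_in, anchors$nrda, "rnr_region")
  cm <- concatenate_markers(pm, rm_)
  expect_equal(ncol(cm), 143 + 189)
  expect_equal(sort(rownames(cm)), c("c1", "c2"))
  expect_equal(attr(cm, "excluded"), "c3")
  # PolA block first: anchor row equals PolA concat window then RNR window
  expect_equal(
    paste(cm["c1", 1:143], collapse = ""),
    substr(anchors$pola$peptide, 784, 926)
  )
  expect_equal(
    paste(cm["c1", 144:332], collapse = ""),
    substr(anchors$nrda$peptide, 437, 625)
  )
})

test_that("clade candidates follow the RNR-class x 762-type map", {
  expect_equal(assign_clade("RNR-I-CyanoSP", "Tyr762")[[1]], 5L)
  expect_equal(assign_clade("RNR-II-RTPR", "Phe762")[[1]], 7L)
  expect_equal(assign_clade("RNR-II-RTPR", "Tyr762")[[1]], 6L)
  expect_equal(assign_clade("RNR-I-Other", "Phe762")[[1]], 4L)
  expect_equal(assign_clade("RNR-I-Other", "Tyr762")[[1]], c(2L, 3L))
  expect_equal(assign_clade("RNR-II-Other", "Tyr762")[[1]], c(1L, 8L))
  expect_equal(assign_clade("RNR-II-Other", "Phe762")[[1]], c(1L, 9L))
  expect_equal(assign_clade("RNR-II-Other", "Leu762")[[1]], 1L)
  # combinations outside the map are unassigned (empty set)
  expect_equal(assign_clade("RNR-I-Other", "Leu762")[[1]], integer())
  expect_equal(assign_clade("RNR-I-CyanoSP", "Phe762")[[1]], integer())
  expect_equal(assign_clade(NA, "Tyr762")[[1]], integer())
  expect_error(assign_clade("RNR-III", "Tyr762"), "Unknown RNR class")
  expect_error(assign_clade("RNR-I-Other", "Trp762"), "Unknown PolA type")
})

test_that("multi-candidate clades resolve by nearest labelled tree neighbour", {
  set.seed(3)
  tr <- ape::read.tree(text = "((q1:0.1,ref2:0.1):0.5,(q2:0.1,ref3:0.1):0.5,ref5:1);")
  labels <- tibble::tibble(contig_id = c("ref2", "ref3"), clade = c(2L, 3L))
  asg <- tibble::tibble(
    contig_id = c("q1", "q2"),
    rnr_class = "RNR-I-Other", pol_type = "Tyr762"
  )
  out <- resolve_clades(asg, tree = tr, labels = labels)
  expect_equal(out$clade, c(2L, 3L))
  expect_equal(out$resolution, c("tree", "tree"))
  # without a tree the candidate set is surfaced instead
  out2 <- resolve_clades(asg)
  expect_true(all(is.na(out2$clade)))
  expect_equal(out2$resolution, c("candidate_set", "candidate_set"))
  expect_equal(out2$candidates[[1]], c(2L, 3L))
})
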