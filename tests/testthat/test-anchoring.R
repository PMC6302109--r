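test_that("global alignment matches a brute-force enumeration oracle on tiny pairs", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:3) {
    q <- paste(sample(aa, 5, replace = TRUE), collapse = "")
    r <- paste(sample(aa, 6, replace = TRUE), collapse = "")
    al <- global_align(q, r)
    expect_equal(al$score, brute_force_best_score(q, r), info = paste(q, r))
    # aligned strings must recover the originals
    expect_equal(gsub("-", "", al$query_aligned), q)
    expect_equal(gsub("-", "", al$ref_aligned), r)
    # no gap-gap column
    qc <- strsplit(al$query_aligned, "")[[1]]
    rc <- strsplit(al$ref_aligned, "")[[1]]
    expect_false(any(qc == "-" & rc == "-"))
  }
})

test_that("identical sequences align gaplessly with an identity map", {
  pep <- rand_pep(30, seed = 3)
  al <- global_align(pep, pep)
  expect_equal(al$query_aligned, pep)
  expect_equal(al$ref_aligned, pep)
  cm <- coordinate_map(al)
  expect_equal(cm$query_pos, cm$ref_pos)
  expect_equal(attr(cm, "query_span"), c(1L, 30L))
})

test_that("an internal deletion shows up as one gap run and 'deleted' map entries", {
  ref <- rand_pep(40, seed = 5)
  q <- paste0(substr(ref, 1, 17), substr(ref, 21, 40)) # delete ref 18..20
  al <- global_align(q, ref)
  expect_equal(stringr::str_count(al$query_aligned, "-+"), 1)
  expect_true(grepl("---", al$query_aligned))
  cm <- coordinate_map(al)
  expect_true(all(is.na(cm$query_pos[18:20])))
  expect_equal(cm$query_pos[17], 17L)
  expect_equal(cm$query_pos[21], 18L)
})

test_that("an insertion shifts downstream mapped query positions", {
  ref <- rand_pep(20, seed = 8)
  q <- paste0(substr(ref, 1, 4), "WWW", substr(ref, 5, 20))
  al <- global_align(q, ref)
  cm <- coordinate_map(al)
  expect_equal(cm$query_pos[4], 4L)
  expect_equal(cm$query_pos[5], 8L)
  expect_equal(cm$query_pos[20], 23L)
})

test_that("classify_762 reads the anchored residue and resolves types", {
  anchor <- anchor_panel()$pola
  # the anchor against itself carries the wild-type phenylalanine
  self <- classify_762(tibble::tibble(id = "self", sequence = anchor$peptide), anchor)
  expect_equal(self$residue762, "F")
  expect_equal(self$pol_type, "Phe762")
  expect_equal(self$coverage, 1)

  # writing Y at the anchored position flips the call to Tyr762
  chars <- strsplit(anchor$peptide, "")[[1]]
  chars[762] <- "Y"
  tyr <- classify_762(tibble::tibble(id = "t", sequence = paste(chars, collapse = "")), anchor)
  expect_equal(tyr$pol_type, "Tyr762")

  # a residue outside {F,Y,L} is Other
  chars[762] <- "K"
  other <- classify_762(tibble::tibble(id = "o", sequence = paste(chars, collapse = "")), anchor)
  expect_equal(other$pol_type, "Other")

  # a fragment that stops before 762 is Unresolved
  frag <- classify_762(
    tibble::tibble(id = "f", sequence = substr(anchor$peptide, 100, 400)), anchor
  )
  expect_equal(frag$pol_type, "Unresolved")
  expect_equal(frag$residue762, "unresolved")
})

test_that("classification is invariant under unrelated flanking padding", {
  anchor <- anchor_panel()$pola
  core <- substr(anchor$peptide, 500, 928)
  base <- classify_762(tibble::tibble(id = "c", sequence = core), anchor)
  padded <- paste0(rand_pep(25, seed = 44), core, substr(rand_pep(31, seed = 45), 2, 31))
  pad <- classify_762(tibble::tibble(id = "p", sequence = padded), anchor)
  expect_equal(base$residue762, "F")
  expect_equal(pad$residue762, base$residue762)
  expect_equal(pad$pol_type, base$pol_type)
})

test_that("the mutator's frozen residue is always recovered at moderate divergence", {
  anchor <- anchor_panel()$pola
  residues <- c("F", "Y", "L", "K")
  set.seed(20)
  for (k in 1:25) {
    div <- stats::runif(1, 0.05, 0.40)
    res <- residues[(k %% 4) + 1]
    chars <- strsplit(anchor$peptide, "")[[1]]
    chars[762] <- res
    pep <- mutate_peptide(paste(chars, collapse = ""), 1 - div, frozen_positions = c(1, 762))
    got <- classify_762(tibble::tibble(id = "m", sequence = pep), anchor)
    expect_equal(got$residue762, res, info = sprintf("divergence %.2f", div))
  }
})

test_that("extract_window returns the anchored regions at the documented lengths", {
  anchors <- anchor_panel()
  part <- extract_window(anchors$pola$peptide, anchors$pola, "partial")
  expect_equal(nchar(part$sequence), 125)
  expect_equal(part$coverage, 1)
  expect_equal(part$sequence, substr(anchors$pola$peptide, 675, 799))

  rnr <- extract_window(anchors$nrda$peptide, anchors$nrda, "rnr_region")
  expect_equal(nchar(rnr$sequence), 189)
  expect_equal(rnr$coverage, 1)

  # 10 deleted window positions: length and coverage drop together
  chars <- strsplit(anchors$pola$peptide, "")[[1]]
  q <- paste(chars[-(700:709)], collapse = "")
  del <- extract_window(q, anchors$pola, "partial")
  expect_equal(nchar(del$sequence), 115)
  expect_equal(del$coverage, 115 / 125)

  expect_error(extract_window("MKL", anchors$pola, "nope"), "no window")
})

test_that("anchor panel round trips through FASTA + sidecar TSV", {
  panel <- anchor_panel()
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_anchor_panel(panel, fa, tsv)
  back <- read_anchor_panel(fa, tsv)
  expect_equal(back$synthetic_pola_anchor$peptide, panel$pola$peptide)
  expect_equal(back$synthetic_pola_anchor$positions, panel$pola$positions)
  expect_equal(back$synthetic_pola_anchor$windows, panel$pola$windows)
  expect_equal(back$synthetic_nrda_anchor$windows, panel$nrda$windows)
})
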