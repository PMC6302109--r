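# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration, recounting and graph search from
# first principles on tiny instances.

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Enumerate every global alignment of q vs r (as aligned string pairs).
# Collects into an environment-backed list to stay usable for a few thousand
# alignments; intended for tiny sequences only.
enumerate_alignments <- function(q, r) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  acc <- new.env()
  acc$out <- vector("list", 8192)
  acc$n <- 0L
  walk <- function(i, j, qa, ra) {
    if (i > length(qc) && j > length(rc)) {
      acc$n <- acc$n + 1L
      if (acc$n > length(acc$out)) acc$out <- c(acc$out, vector("list", length(acc$out)))
      acc$out[[acc$n]] <- list(
        qa = paste(qa, collapse = ""),
        ra = paste(ra, collapse = "")
      )
      return(invisible())
    }
    if (i <= length(qc) && j <= length(rc)) {
      walk(i + 1L, j + 1L, c(qa, qc[i]), c(ra, rc[j]))
    }
    if (i <= length(qc)) {
      walk(i + 1L, j, c(qa, qc[i]), c(ra, "-"))
    }
    if (j <= length(rc)) {
      walk(i, j + 1L, c(qa, "-"), c(ra, rc[j]))
    }
    invisible()
  }
  walk(1L, 1L, character(), character())
  acc$out[seq_len(acc$n)]
}

# Score one aligned string pair under BLOSUM62 with affine gaps
# (run cost = open + len * ext) and free terminal gap runs on both rows.
score_alignment_endsfree <- function(qa, ra, open = 11, ext = 1) {
  B <- blosum62_matrix()
  qc <- strsplit(qa, "")[[1]]
  rc <- strsplit(ra, "")[[1]]
  n <- length(qc)
  score <- 0
  run_cost <- function(chars) {
    cost <- 0
    i <- 1
    while (i <= n) {
      if (chars[i] == "-") {
        j <- i
        while (j < n && chars[j + 1] == "-") j <- j + 1
        terminal <- (i == 1) || (j == n)
        if (!terminal) cost <- cost + open + ext * (j - i + 1)
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    cost
  }
  for (k in seq_len(n)) {
    if (qc[k] != "-" && rc[k] != "-") score <- score + B[qc[k], rc[k]]
  }
  score - run_cost(qc) - run_cost(rc)
}

# Optimal ends-free score by exhaustive enumeration (tiny sequences only).
brute_force_best_score <- function(q, r, open = 11, ext = 1) {
  max(vapply(
    enumerate_alignments(q, r),
    function(al) score_alignment_endsfree(al$qa, al$ra, open, ext),
    numeric(1)
  ))
}

# Recount pairwise anchored identity per the documented rule, one pair at a
# time: columns inside either row's residue span with >= 1 residue.
recount_identity <- function(row_i, row_j) {
  span <- function(x) {
    w <- which(x != "-")
    if (!length(w)) return(c(Inf, -Inf))
    range(w)
  }
  si <- span(row_i)
  sj <- span(row_j)
  matches <- 0
  denom <- 0
  for (c in seq_along(row_i)) {
    a <- row_i[c]
    b <- row_j[c]
    a_counts <- a != "-" && c >= sj[1] && c <= sj[2]
    b_counts <- b != "-" && c >= si[1] && c <= si[2]
    both <- a != "-" && b != "-"
    if (both || a_counts || b_counts) denom <- denom + 1
    if (both && a == b) matches <- matches + 1
  }
  if (denom == 0) return(0)
  matches / denom
}

# Connected components by breadth-first search over an edge list.
bfs_components <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    a <- edges$from[k]
    b <- edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  cur <- 0L
  for (s in ids) {
    if (!is.na(comp[[s]])) next
    cur <- cur + 1L
    queue <- s
    comp[[s]] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(comp[[w]])) {
          comp[[w]] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# Small deterministic peptide helpers.
rand_pep <- function(n, seed) {
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  set.seed(seed)
  paste(c("M", sample(aa, n - 1, replace = TRUE)), collapse = "")
}

# A tiny hand-controllable anchor used by unit tests (independent of the
# bundled panel).
toy_anchor <- function(len = 40, pos = 20, windows = list(win = c(10L, 29L))) {
  pep <- rand_pep(len, seed = 99)
  chars <- strsplit(pep, "")[[1]]
  chars[pos] <- "F"
  reference_anchor("toy", paste(chars, collapse = ""),
    positions = c(pos762 = as.integer(pos)), windows = windows
  )
}
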