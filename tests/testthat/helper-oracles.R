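## Independent oracles used to validate the package's algorithmic core.
## Everything here is written naively (loops, exhaustive enumeration) and
## deliberately shares no code with the implementation under test.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

oracle_compat <- function(p, b) b %in% ORACLE_IUPAC[[p]]

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

## all-offsets, all-strands naive binding-site scan
oracle_binding_sites <- function(template, pseq, frac = 0.10, w = 1L) {
  tv <- strsplit(template, "")[[1]]
  n <- length(tv)
  k <- nchar(pseq)
  max_internal <- floor(frac * k)
  hits <- list()
  for (strand in c("+", "-")) {
    pv <- strsplit(if (strand == "+") pseq else oracle_revcomp(pseq),
                   "")[[1]]
    tail_idx <- if (strand == "+") (k - w + 1L):k else 1L:w
    for (s in seq_len(max(0L, n - k + 1L))) {
      cmp <- !mapply(oracle_compat, pv, tv[s:(s + k - 1L)])
      if (any(cmp[tail_idx])) next
      if (sum(cmp[-tail_idx]) > max_internal) next
      hits[[length(hits) + 1L]] <- data.frame(start = s, end = s + k - 1L,
                                              strand = strand)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), end = integer(), strand = character())
}

## Gotoh affine-gap DP, gap run of length L costs open + L * extend;
## returns the optimal score only
oracle_gotoh <- function(a, b, type = c("overlap", "global"),
                         match = 1, mismatch = -1,
                         gap_open = 4, gap_extend = 1) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  go <- gap_open + gap_extend  # cost of a length-1 gap
  M <- Ix <- Iy <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  for (i in seq_len(n))
    Ix[i + 1L, 1L] <- if (type == "overlap") 0 else
      -(gap_open + i * gap_extend)
  for (j in seq_len(m))
    Iy[1L, j + 1L] <- if (type == "overlap") 0 else
      -(gap_open + j * gap_extend)
  if (type == "overlap") {
    M[, 1L] <- pmax(M[, 1L], Ix[, 1L])
    M[1L, ] <- pmax(M[1L, ], Iy[1L, ])
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - go, Iy[i, j + 1L] - go,
                                Ix[i, j + 1L] - gap_extend)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - go, Ix[i + 1L, j] - go,
                                Iy[i + 1L, j] - gap_extend)
    }
  }
  if (type == "global") return(max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L],
                                   Iy[n + 1L, m + 1L]))
  ## overlap: best over last row and last column, end gaps free
  best <- max(M[n + 1L, ], M[, m + 1L])
  best
}

## every partition of 1..n into k non-empty unordered blocks
oracle_partitions <- function(n, k) {
  out <- list()
  assign_next <- function(labels, i, used) {
    if (i > n) {
      if (used == k) out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (g in seq_len(min(used + 1L, k))) {
      labels[i] <- g
      assign_next(labels, i + 1L, max(used, g))
    }
  }
  assign_next(integer(n), 1L, 0L)
  out
}

## best k-partition under the complete-linkage objective
oracle_min_max_diameter_partition <- function(pts, k) {
  n <- nrow(pts)
  dmat <- as.matrix(dist(pts))
  best <- NULL; best_obj <- Inf
  for (p in oracle_partitions(n, k)) {
    diam <- max(vapply(seq_len(k), function(g) {
      ix <- which(p == g)
      if (length(ix) < 2L) 0 else max(dmat[ix, ix])
    }, 0))
    if (diam < best_obj) { best_obj <- diam; best <- p }
  }
  list(partition = best, objective = best_obj)
}

## random stop-free ORF for test construction (independent of the
## package's generator)
oracle_random_orf <- function(n_codons) {
  codons <- c()
  all3 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste, collapse = "")
  ok <- setdiff(all3, c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(ok, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

random_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                                collapse = "")

## split keys of a phylo tree, for topology comparison against ape
oracle_split_keys <- function(tree) {
  names(bipartitions(tree))
}
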