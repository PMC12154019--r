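#' Alignment container
#'
#' A minimal multiple-alignment object: equal-length gapped strings with
#' sample ids and optional gene-partition bookkeeping (used by
#' [concatenate_alignments()] to keep per-gene column ranges
#' recoverable).
#'
#' @param seqs named character vector of equal-length gapped sequences
#'   (gap character `-`).
#' @param partitions optional data frame with columns `gene`, `start`,
#'   `end` (1-based inclusive column ranges).
#' @return an object of class `cannatype_alignment`.
#' @export
new_alignment <- function(seqs, partitions = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows must all have the same length", call. = FALSE)
  structure(list(ids = names(seqs), seqs = seqs, partitions = partitions),
            class = "cannatype_alignment")
}

#' @export
print.cannatype_alignment <- function(x, ...) {
  cat("Alignment of", length(x$seqs), "sequences,",
      nchar(x$seqs[[1]]), "columns\n")
  if (!is.null(x$partitions)) {
    cat("partitions:",
        paste(sprintf("%s[%d-%d]", x$partitions$gene, x$partitions$start,
                      x$partitions$end), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
#' @method as.matrix cannatype_alignment
as.matrix.cannatype_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(toupper(x$seqs), "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

#' Number of columns of an alignment
#' @param alignment a `cannatype_alignment`.
#' @return integer column count.
#' @export
alignment_length <- function(alignment) {
  stopifnot(inherits(alignment, "cannatype_alignment"))
  nchar(alignment$seqs[[1]])
}

#' Extract one gene's columns from a concatenated alignment
#' @param alignment a `cannatype_alignment` with partitions.
#' @param gene partition name.
#' @return a `cannatype_alignment` restricted to that gene's columns.
#' @export
alignment_partition <- function(alignment, gene) {
  p <- alignment$partitions
  if (is.null(p) || !gene %in% p$gene)
    stop("no partition named '", gene, "'", call. = FALSE)
  i <- match(gene, p$gene)
  new_alignment(substring(alignment$seqs, p$start[i], p$end[i]))
}

#' Star-progressive multiple alignment
#'
#' Aligns every sequence pairwise (global, affine gaps; see
#' [pairwise_align()]) to a common center — the first sequence — and
#' merges the pairwise alignments under the usual "once a gap, always a
#' gap" rule: each inter-residue slot of the center receives the maximum
#' number of inserted columns required by any sequence.  Deterministic
#' given input order.
#'
#' @param seqs named character vector or `DNAStringSet` of at least two
#'   ungapped nucleotide sequences.
#' @param ... scoring parameters passed to [pairwise_align()].
#' @return a `cannatype_alignment` (center first).
#' @export
align_progressive <- function(seqs, ...) {
  seqs <- as_named_chr(seqs)
  if (length(seqs) < 2L) stop("need at least two sequences", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named", call. = FALSE)
  center <- seqs[[1L]]
  L <- nchar(center)
  others <- seqs[-1L]

  ## per sequence: chars aligned to each center residue + insertion blocks
  parsed <- lapply(others, function(s) {
    aln <- pairwise_align(center, s, type = "global", ...)
    ca <- strsplit(aln$a_aligned, "", fixed = TRUE)[[1]]
    sa <- strsplit(aln$b_aligned, "", fixed = TRUE)[[1]]
    is_gap <- ca == "-"
    slot <- cumsum(!is_gap)             # 0..L, insertion slot index
    blocks <- split(sa[is_gap], slot[is_gap])
    list(chars = sa[!is_gap],
         blocks = blocks,
         ins = {
           v <- integer(L + 1L)
           if (length(blocks))
             v[as.integer(names(blocks)) + 1L] <- lengths(blocks)
           v
         })
  })
  ins <- Reduce(pmax, lapply(parsed, `[[`, "ins"), integer(L + 1L))

  weave <- function(chars, blocks, my_ins) {
    blk <- strrep("-", ins)
    if (length(blocks)) {
      at <- as.integer(names(blocks)) + 1L
      blk[at] <- paste0(vapply(blocks, paste, "", collapse = ""),
                        strrep("-", ins[at] - my_ins[at]))
    }
    paste0(paste0(blk[seq_len(L)], chars, collapse = ""), blk[L + 1L])
  }
  center_row <- weave(strsplit(center, "", fixed = TRUE)[[1]],
                      list(), integer(L + 1L))
  rows <- vapply(parsed, function(p) weave(p$chars, p$blocks, p$ins), "")
  out <- c(center_row, rows)
  names(out) <- c(names(seqs)[1L], names(others))
  new_alignment(out)
}

#' Concatenate per-gene alignments column-wise
#'
#' @param alignments named list of `cannatype_alignment` objects over the
#'   same sample set.
#' @param gap_fill if `TRUE`, a sample missing from one gene is filled
#'   with gap columns for that gene instead of raising an error.
#' @return a `cannatype_alignment` whose `partitions` record each gene's
#'   column range.
#' @export
concatenate_alignments <- function(alignments, gap_fill = FALSE) {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)))
  ids <- Reduce(union, lapply(alignments, `[[`, "ids"))
  if (!gap_fill) {
    for (g in names(alignments)) {
      missing <- setdiff(ids, alignments[[g]]$ids)
      if (length(missing))
        stop("sample(s) absent from gene '", g, "': ",
             paste(missing, collapse = ", "),
             " (use gap_fill = TRUE to pad)", call. = FALSE)
    }
  }
  widths <- vapply(alignments, alignment_length, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(ids, function(id) {
    paste(vapply(names(alignments), function(g) {
      a <- alignments[[g]]
      if (id %in% a$ids) a$seqs[[match(id, a$ids)]]
      else strrep("-", alignment_length(a))
    }, ""), collapse = "")
  }, "")
  names(rows) <- ids
  new_alignment(rows, partitions = data.frame(
    gene = names(alignments), start = unname(starts), end = unname(ends)))
}

#' Pool per-gene alignments into one block-diagonal alignment
#'
#' Stacks the rows of several alignments side by side so that different
#' gene copies become separate rows of a single supermatrix: each row
#' keeps its own columns and is gap-filled across the other genes'
#' columns.  This is how a tree over *gene copies* (rather than samples)
#' is built when the gene families are too diverged for a meaningful
#' cross-family alignment; pair it with
#' `jc69_distance(..., allow_zero_overlap = TRUE)`, under which
#' cross-family pairs sit at the saturation cap.
#'
#' @param alignments named list of `cannatype_alignment` objects with
#'   mutually disjoint row ids (e.g. `"<sample>|THCAS"` vs
#'   `"<sample>|CBDAS"`).
#' @return a `cannatype_alignment` with per-gene partitions.
#' @export
pool_alignments <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L,
            !is.null(names(alignments)))
  ids <- unlist(lapply(alignments, `[[`, "ids"), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("row ids must be disjoint across pooled alignments", call. = FALSE)
  widths <- vapply(alignments, alignment_length, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  total <- sum(widths)
  rows <- unlist(lapply(seq_along(alignments), function(k) {
    a <- alignments[[k]]
    pre <- strrep("-", starts[k] - 1L)
    post <- strrep("-", total - ends[k])
    stats::setNames(paste0(pre, a$seqs, post), a$ids)
  }))
  new_alignment(rows, partitions = data.frame(
    gene = names(alignments), start = unname(starts), end = unname(ends)))
}

## mismatch fraction matrix over mutually ungapped A/C/G/T columns,
## computed with one-hot crossproducts so bootstrap replicates stay cheap
p_distance_matrix <- function(M) {
  n <- nrow(M)
  match_counts <- matrix(0, n, n)
  V <- matrix(0, n, ncol(M))
  for (b in c("A", "C", "G", "T")) {
    Xb <- (M == b) * 1
    match_counts <- match_counts + tcrossprod(Xb)
    V <- V + Xb
  }
  overlap <- tcrossprod(V)
  p <- 1 - match_counts / ifelse(overlap == 0, NA_real_, overlap)
  diag(p) <- 0
  dimnames(p) <- list(rownames(M), rownames(M))
  attr(p, "overlap") <- overlap
  p
}

#' Pairwise evolutionary distances from an alignment
#'
#' Mismatch fraction p is computed over mutually ungapped columns; under
#' the Jukes–Cantor (JC69) model the distance is
#' `d = -(3/4) * log(1 - (4/3) * p)`.  Pairs with `p >= 0.75` are beyond
#' what JC69 can express (saturated); their distance is capped at
#' `saturation_cap` and flagged.
#'
#' @param alignment a `cannatype_alignment`.
#' @param model `"JC69"` (default) or `"p"` (raw mismatch fraction).
#' @param saturation_cap distance substituted for saturated pairs.
#' @param allow_zero_overlap by default a pair with no mutually ungapped
#'   column is an error (naming the pair); with `TRUE` such pairs are
#'   treated as saturated instead — the supermatrix convention for
#'   non-overlapping partitions (see [pool_alignments()]).
#' @return symmetric numeric matrix with zero diagonal; attributes
#'   `"model"` and `"saturated"` (logical matrix).
#' @export
jc69_distance <- function(alignment, model = c("JC69", "p"),
                          saturation_cap = 5, allow_zero_overlap = FALSE) {
  model <- match.arg(model)
  p <- p_distance_matrix(as.matrix(alignment))
  none <- is.na(p)
  if (any(none) && !allow_zero_overlap) {
    ij <- which(none, arr.ind = TRUE)[1L, ]
    stop("no mutually ungapped columns between '", rownames(p)[ij[1L]],
         "' and '", rownames(p)[ij[2L]], "'", call. = FALSE)
  }
  p[none] <- 1
  if (model == "p") {
    d <- p
    sat <- none
  } else {
    sat <- p >= 0.75
    d <- suppressWarnings(-0.75 * log(1 - (4 / 3) * p))
    d[sat] <- saturation_cap
    diag(d) <- 0
  }
  dimnames(sat) <- dimnames(p)
  attr(d, "overlap") <- NULL
  attr(d, "model") <- model
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining (Q criterion with Studier–Keppler distance
#' updates).  Ties on the Q criterion are broken deterministically by the
#' lexicographically smallest pair of cluster representative ids (the
#' smallest original label inside each cluster).  Negative branch lengths
#' are clamped to zero and counted in the `"negative_clamped"` attribute.
#' On an additive (tree-metric) matrix NJ recovers the generating
#' topology and branch lengths exactly.
#'
#' @param D symmetric distance matrix with row/column names, >= 3 taxa.
#' @return an unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("'D' must be a square matrix", call. = FALSE)
  if (is.null(rownames(D)))
    stop("'D' must have row/column names", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8)
    stop("'D' is asymmetric", call. = FALSE)
  m <- nrow(D)
  if (m < 3L) stop("need at least 3 taxa", call. = FALSE)
  D <- (D + t(D)) / 2
  nodes <- rownames(D)
  reps <- rownames(D)
  nclamp <- 0L
  clamp <- function(x) {
    if (x < 0) { nclamp <<- nclamp + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (m > 3L) {
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    lo <- pmin(reps[cand[, 1L]], reps[cand[, 2L]])
    hi <- pmax(reps[cand[, 1L]], reps[cand[, 2L]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    dij <- D[i, j]
    bi <- clamp(dij / 2 + (R[i] - R[j]) / (2 * (m - 2)))
    bj <- clamp(dij - (dij / 2 + (R[i] - R[j]) / (2 * (m - 2))))
    newnode <- paste0("(", nodes[i], ":", fmt(bi), ",",
                      nodes[j], ":", fmt(bj), ")")
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], newnode)
    reps <- c(reps[keep], min(reps[i], reps[j]))
    rownames(D) <- colnames(D) <- reps
    m <- m - 1L
  }
  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- paste0("(", nodes[1], ":", fmt(b1), ",", nodes[2], ":", fmt(b2),
                ",", nodes[3], ":", fmt(b3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_clamped") <- nclamp
  tree
}

## canonical key of the split defined by `tips`, relative to the full
## label set: the side not containing the alphabetically first label
split_key <- function(tips, labels) {
  side <- if (min(labels) %in% tips) setdiff(labels, tips) else tips
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; splits separating fewer
#' than two leaves are trivial and omitted.
#'
#' @param tree a `phylo` object.
#' @return named list of character vectors (tip labels of the canonical
#'   side); names are stable keys usable for comparison across trees.
#' @export
bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  n <- length(labels)
  pp <- ape::prop.part(tree)
  sets <- lapply(pp[-1L], function(ix) labels[ix])
  sets <- Filter(function(s) length(s) >= 2L && length(s) <= n - 2L, sets)
  keys <- vapply(sets, split_key, "", labels = labels)
  sets <- lapply(sets, function(s) {
    if (min(labels) %in% s) setdiff(labels, s) else sort(s)
  })
  names(sets) <- keys
  sets[!duplicated(keys)]
}

#' Does a tree contain a given clade?
#'
#' In the unrooted sense: the tip set (or its complement) corresponds to
#' one side of some internal edge.  Trivial groups (fewer than two tips,
#' or fewer than two tips outside) are always present.
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
has_clade <- function(tree, tips) {
  labels <- tree$tip.label
  if (!all(tips %in% labels))
    stop("unknown tip(s): ", paste(setdiff(tips, labels), collapse = ", "),
         call. = FALSE)
  n <- length(labels)
  if (length(tips) < 2L || length(tips) > n - 2L) return(TRUE)
  split_key(tips, labels) %in% names(bipartitions(tree))
}

#' Column-resampling bootstrap for a neighbor-joining tree
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times, rebuilds the NJ tree
#' from each resampled alignment, and records every replicate's
#' bipartitions.  Support of a split is the fraction of replicate trees
#' containing it.
#'
#' @param alignment a `cannatype_alignment`.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed making the resampling reproducible; the
#'   caller's RNG state is left untouched.
#' @param model distance model, see [jc69_distance()].
#' @param ... further arguments to [jc69_distance()] (e.g.
#'   `allow_zero_overlap` for pooled gene-copy alignments).
#' @return object of class `nj_bootstrap`: list with `tree`, `splits`
#'   (bipartitions of the main tree), `support` (named fraction per main
#'   split), `replicate_splits` (list of key vectors) and `n_replicates`.
#' @export
bootstrap_support <- function(alignment, n_replicates = 100, seed = NULL,
                              model = c("JC69", "p"), ...) {
  model <- match.arg(model)
  stopifnot(n_replicates >= 1)
  M <- as.matrix(alignment)
  main <- nj_tree(jc69_distance(alignment, model = model, ...))
  main_splits <- bipartitions(main)
  rep_keys <- local_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      idx <- sample.int(ncol(M), replace = TRUE)
      Mr <- M[, idx, drop = FALSE]
      ar <- new_alignment(apply(Mr, 1L, paste, collapse = ""))
      names(bipartitions(nj_tree(jc69_distance(ar, model = model, ...))))
    })
  })
  support <- vapply(names(main_splits), function(k) {
    mean(vapply(rep_keys, function(ks) k %in% ks, TRUE))
  }, 0)
  structure(list(tree = main, splits = main_splits, support = support,
                 replicate_splits = rep_keys, n_replicates = n_replicates),
            class = "nj_bootstrap")
}

#' @export
print.nj_bootstrap <- function(x, ...) {
  cat("NJ tree with", length(x$tree$tip.label), "tips;",
      length(x$splits), "internal splits;", x$n_replicates,
      "bootstrap replicates\n")
  if (length(x$support))
    cat("split supports:",
        paste(sprintf("%.2f", sort(unname(x$support))), collapse = " "),
        "\n")
  invisible(x)
}

#' Bootstrap support of an arbitrary clade
#'
#' Fraction of bootstrap replicate trees containing the given split,
#' whether or not the main tree contains it.
#'
#' @param bs an `nj_bootstrap` object.
#' @param tips character vector of tip labels.
#' @return numeric fraction in `[0, 1]`.
#' @export
clade_support <- function(bs, tips) {
  stopifnot(inherits(bs, "nj_bootstrap"))
  labels <- bs$tree$tip.label
  n <- length(labels)
  if (length(tips) < 2L || length(tips) > n - 2L) return(1)
  key <- split_key(tips, labels)
  mean(vapply(bs$replicate_splits, function(ks) key %in% ks, TRUE))
}

#' Mean patristic distances between leaf groups
#'
#' Summarises how far apart named groups of leaves sit on a tree, as the
#' mean patristic (path-length) distance between members of different
#' groups.
#'
#' @param tree a `phylo` object.
#' @param groups named list of tip-label vectors.
#' @return symmetric matrix of mean between-group distances (diagonal:
#'   mean within-group distance, 0 for singletons).
#' @export
clade_separation <- function(tree, groups) {
  stopifnot(inherits(tree, "phylo"), is.list(groups), !is.null(names(groups)))
  cp <- stats::cophenetic(tree)
  k <- length(groups)
  out <- matrix(0, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    block <- cp[groups[[i]], groups[[j]], drop = FALSE]
    if (i == j) {
      out[i, j] <- if (length(groups[[i]]) > 1L)
        mean(block[upper.tri(block)]) else 0
    } else out[i, j] <- mean(block)
  }
  out
}
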