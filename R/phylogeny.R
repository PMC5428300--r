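#' Neighbor-joining tree from a difference matrix
#'
#' Canonical neighbor joining (Saitou & Nei, as corrected by Studier &
#' Keppler) on p-distances. When given a `diff_matrix` the distances are
#' `counts / denominator` (unrounded). Deterministic: ties in the Q
#' criterion are broken by the lowest pair of node indices (original taxon
#' order, merged nodes appended after). Negative branch-length estimates
#' are clamped to zero with a warning.
#'
#' @param dm a [pairwise_difference_matrix()] result, a symmetric numeric
#'   matrix with dimnames, or a `dist`.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "diff_matrix")) {
    d <- dm$counts / dm$denominator
    diag(d) <- 0
  } else if (inherits(dm, "dist")) {
    d <- as.matrix(dm)
  } else {
    d <- as.matrix(dm)
  }
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix is not symmetric")
  labels <- rownames(d) %||% paste0("t", seq_len(n))

  clamped <- FALSE
  fmt_len <- function(x) {
    if (x < 0) { clamped <<- TRUE; x <- 0 }
    sprintf("%.10g", x)
  }
  nodes <- labels           # newick fragment per active node
  act <- seq_len(n)         # original index order for tie-breaking
  D <- d
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(D)
    best <- NULL; best_q <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) { best_q <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    new_frag <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt_len(li),
                        nodes[j], fmt_len(lj))
    dnew <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], new_frag)
    act <- c(act[keep], max(act) + 1L)
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1L], fmt_len(l1),
                    nodes[2L], fmt_len(l2), nodes[3L], fmt_len(l3))
  if (clamped) warning("negative branch length estimate(s) clamped to 0")
  ape::read.tree(text = newick)
}

# non-trivial bipartitions of an unrooted tree, as canonical strings:
# the side NOT containing the alphabetically first tip, tips sorted and
# joined with "|"
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character())
  nnode <- tree$Nnode
  ref <- sort(tree$tip.label)[1L]
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  edge <- tree$edge[order(tree$edge[, 1L], decreasing = TRUE), , drop = FALSE]
  # children appear after parents in postorder over decreasing node ids
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- ntip + 1L
  internal <- setdiff(unique(tree$edge[, 2L]), seq_len(ntip))
  out <- vapply(internal, function(nd) {
    side <- desc[[nd]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(side) > ntip - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(out[!is.na(out)])
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the internal (non-trivial) bipartition sets of
#' two unrooted trees over the identical leaf set.
#'
#' @param a,b `phylo` trees with identical tip labels.
#' @return integer RF distance.
#' @export
rf_distance <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have different leaf sets")
  ba <- tree_bipartitions(a)
  bb <- tree_bipartitions(b)
  length(setdiff(ba, bb)) + length(setdiff(bb, ba))
}

#' Column-bootstrap support for a neighbor-joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times, rebuilding the difference matrix and NJ tree
#' per replicate; the support of each internal edge of the full-data tree is
#' the percentage of replicates whose tree contains that bipartition.
#' Column resampling is performed on compressed site patterns (identical
#' columns are interchangeable under iid resampling), so runtime is
#' independent of alignment length beyond the initial scan. A fixed seed
#' yields bit-identical results.
#'
#' @param x an `msa`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param mode denominator mode passed to [pairwise_difference_matrix()].
#' @return the full-data NJ tree with integer support percents as
#'   `node.label` (root label empty). Alignments with fewer than 4 taxa
#'   return the tree without support values.
#' @export
bootstrap_support <- function(x, n_reps = 1000L, seed = 1L,
                              mode = "alignment_length") {
  stopifnot(inherits(x, "msa"), n_reps >= 1L)
  dm_full <- pairwise_difference_matrix(x, mode = mode)
  tree <- nj_tree(dm_full)
  n <- length(x$taxa)
  if (n < 4L) return(tree)

  mat <- msa_matrix(x)
  L <- ncol(mat)
  # site-pattern compression
  enc <- matrix(match(mat, c("A", "C", "G", "T", "N", "-")), nrow = n)
  if (n <= 19L) {
    code <- as.vector(6^(seq_len(n) - 1L) %*% (enc - 1L))
  } else {
    code <- apply(enc, 2L, paste, collapse = ",")
  }
  u <- !duplicated(code)
  pat_id <- match(code, code[u])
  pat_count <- tabulate(pat_id, nbins = sum(u))
  pat <- mat[, u, drop = FALSE]
  P <- ncol(pat)
  ok <- pat == "A" | pat == "C" | pat == "G" | pat == "T"
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  diff_ind <- matrix(0, P, nrow(pairs))   # per-pattern difference indicator
  ok_ind <- matrix(0, P, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    both <- ok[i, ] & ok[j, ]
    diff_ind[, k] <- as.numeric(both & (pat[i, ] != pat[j, ]))
    ok_ind[, k] <- as.numeric(both)
  }

  bip_full <- tree_bipartitions(tree)
  hit <- setNames(integer(length(bip_full)), bip_full)
  set.seed(seed)
  for (rep in seq_len(n_reps)) {
    w <- as.vector(rmultinom(1L, L, pat_count))
    cnt <- as.vector(crossprod(diff_ind, w))
    den <- if (mode == "alignment_length") L
           else as.vector(crossprod(ok_ind, w))
    dvec <- cnt / den
    dvec[!is.finite(dvec)] <- 0
    D <- matrix(0, n, n, dimnames = list(x$taxa, x$taxa))
    D[cbind(pairs[, 1L], pairs[, 2L])] <- dvec
    D <- D + t(D)
    rep_bip <- tree_bipartitions(suppressWarnings(nj_tree(D)))
    seen <- bip_full %in% rep_bip
    hit[seen] <- hit[seen] + 1L
  }
  support <- round(100 * hit / n_reps)

  # attach supports as node labels on the full-data tree
  ntip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  ref <- sort(tree$tip.label)[1L]
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  edge <- tree$edge[order(tree$edge[, 1L], decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(edge)))
    desc[[edge[k, 1L]]] <- c(desc[[edge[k, 1L]]], desc[[edge[k, 2L]]])
  for (nd in setdiff(unique(tree$edge[, 2L]), seq_len(ntip))) {
    side <- desc[[nd]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support))
      labels[nd - ntip] <- as.character(support[[key]])
  }
  tree$node.label <- labels
  attr(tree, "n_reps") <- n_reps
  tree
}

# phylo -> nested list (tips as label/length leaves), for edge contraction
phylo_to_list <- function(tree) {
  ntip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  has_len <- !is.null(tree$edge.length)
  build <- function(node, len) {
    if (node <= ntip)
      return(list(tip = TRUE, label = tree$tip.label[node], length = len))
    kids <- lapply(children[[as.character(node)]], function(e)
      build(tree$edge[e, 2L], if (has_len) tree$edge.length[e] else NA))
    sup <- if (!is.null(tree$node.label)) tree$node.label[node - ntip] else ""
    list(tip = FALSE, label = sup, length = len, children = kids)
  }
  build(length(tree$tip.label) + 1L, NA)
}

list_to_newick <- function(node) {
  fmt <- function(nd) {
    lab <- if (nd$tip) nd$label else {
      paste0("(", paste(vapply(nd$children, fmt, character(1)),
                        collapse = ","), ")", nd$label)
    }
    if (is.na(nd$length)) lab else sprintf("%s:%.6g", lab, nd$length)
  }
  paste0(fmt(node), ";")
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal edge whose bootstrap support is below
#' `threshold` percent, splicing the children of the collapsed node into its
#' parent (the contracted edge's length is dropped; children keep their own
#' branch lengths). The leaf set is unchanged. Collapsing at threshold 0 is
#' the identity; at a threshold above 100 every internal edge collapses and
#' a star tree results.
#'
#' @param tree a `phylo` with numeric support values in `node.label`.
#' @param threshold support percent below which an edge is contracted.
#' @return the collapsed `phylo`.
#' @export
collapse_low_support <- function(tree, threshold = 50) {
  if (is.null(tree$node.label))
    stop("tree has no support values (node.label)")
  root <- phylo_to_list(tree)
  contract <- function(nd) {
    if (nd$tip) return(nd)
    nd$children <- lapply(nd$children, contract)
    kids <- list()
    for (ch in nd$children) {
      sup <- suppressWarnings(as.numeric(ch$label))
      if (!ch$tip && !is.na(sup) && sup < threshold) {
        kids <- c(kids, ch$children)
      } else {
        kids <- c(kids, list(ch))
      }
    }
    nd$children <- kids
    nd
  }
  ape::read.tree(text = list_to_newick(contract(root)))
}

#' Write a tree with support labels to a Newick file
#' @param tree a `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree_file <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Test whether a tree contains a clade
#' @param tree a `phylo`.
#' @param tips character vector of tip labels.
#' @return `TRUE` when some internal edge splits exactly `tips` from the
#'   rest of the leaf set.
#' @export
has_clade <- function(tree, tips) {
  ref <- sort(tree$tip.label)[1L]
  side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
  paste(sort(side), collapse = "|") %in% tree_bipartitions(tree)
}
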