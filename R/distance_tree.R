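#' Euclidean distance between two fingerprints
#'
#' The proteome-architecture distance: the Euclidean distance between the two
#' normalized density grids, `r_AB = sqrt(sum_ij (A_ij - B_ij)^2)`, taken over
#' all M x N blocks. Because densities are normalized, the distance is at most
#' `sqrt(2)` (attained by disjointly supported grids) and is typically small
#' — branch lengths of resulting trees live on a scale of ~0.01.
#'
#' @param a,b `ld_fingerprint` objects on the same partition.
#' @return A non-negative number.
#' @export
fingerprint_distance <- function(a, b) {
  stopifnot(inherits(a, "ld_fingerprint"), inherits(b, "ld_fingerprint"))
  if (!same_partition(a$partition, b$partition)) {
    stop("fingerprints use different partitions")
  }
  sqrt(sum((a$density - b$density)^2))
}

#' Pairwise distance matrix over a set of fingerprints
#'
#' @param fps List of `ld_fingerprint` objects (>= 2, distinct names, shared
#'   partition).
#' @return An object of class `ld_distmat`: a symmetric numeric matrix with
#'   zero diagonal and the fingerprint names as dimnames.
#' @export
fingerprint_distance_matrix <- function(fps) {
  if (length(fps) < 2) {
    stop("need at least 2 fingerprints")
  }
  labels <- vapply(fps, function(f) f$name, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate fingerprint labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  n <- length(fps)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- fingerprint_distance(fps[[i]], fps[[j]])
    }
  }
  structure(d, class = c("ld_distmat", "matrix"))
}

as_distmat <- function(d) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  stopifnot(nrow(d) == ncol(d))
  if (any(!is.finite(d))) {
    stop("distance matrix contains non-finite entries")
  }
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with a zero diagonal")
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining, implemented in-package: at each step
#' the pair `(i, j)` minimizing `Q_ij = (r - 2) d_ij - R_i - R_j` (with `R_i`
#' the row sum over the `r` active clusters) is joined; branch lengths follow
#' the standard formulas and the matrix is reduced until three clusters
#' remain, which are joined in a final trifurcation. The result is an
#' *unrooted* tree.
#'
#' Determinism: when several pairs tie for the minimal `Q` (beyond numerical
#' noise), the pair whose representative labels are lexicographically smallest
#' is joined, so the same matrix always yields the same tree. Negative branch
#' length estimates are clamped to zero and the deficit moved to the sister
#' branch (the usual adjustment), keeping the path length between the joined
#' pair intact.
#'
#' @param d An `ld_distmat`, `dist`, or labelled symmetric matrix with >= 3
#'   taxa.
#' @return An [ape::phylo] tree (unrooted) over the matrix labels.
#' @export
nj_tree <- function(d) {
  d <- as_distmat(d)
  n <- nrow(d)
  if (n < 3) {
    stop("neighbor joining needs at least 3 taxa")
  }
  labels <- rownames(d)

  # each active cluster: its partial Newick string, and its representative
  # (lexicographically smallest leaf label) for tie-breaking
  newick <- labels
  rep_lab <- labels
  active <- seq_len(n)

  fmt <- function(x) formatC(x, digits = 12, format = "g")

  while (length(active) > 3) {
    r <- length(active)
    dd <- d[active, active, drop = FALSE]
    R <- rowSums(dd)
    Q <- (r - 2) * dd - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand) > 1) {
      key <- apply(cand, 1, function(p) {
        lab <- sort(c(rep_lab[active[p[1]]], rep_lab[active[p[2]]]))
        paste(lab, collapse = "\r")
      })
      cand <- cand[order(key)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    ai <- active[i]; aj <- active[j]

    vi <- dd[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- dd[i, j] - vi
    # clamp negatives, transferring the deficit to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)

    others <- active[-c(i, j)]
    dnew <- (d[ai, others] + d[aj, others] - d[ai, aj]) / 2

    # reuse slot ai for the merged cluster
    d[ai, others] <- dnew
    d[others, ai] <- dnew
    d[ai, ai] <- 0
    newick[ai] <- paste0("(", newick[ai], ":", fmt(vi), ",",
                         newick[aj], ":", fmt(vj), ")")
    rep_lab[ai] <- min(rep_lab[ai], rep_lab[aj])
    active <- active[-j]
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  va <- (d[a, b] + d[a, c3] - d[b, c3]) / 2
  vb <- (d[a, b] + d[b, c3] - d[a, c3]) / 2
  vc <- (d[a, c3] + d[b, c3] - d[a, b]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  nwk <- paste0("(", newick[a], ":", fmt(va), ",", newick[b], ":", fmt(vb),
                ",", newick[c3], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = nwk)
  tree
}

#' Does a label set form a clade of the unrooted tree?
#'
#' True if and only if some edge of the unrooted tree bipartitions the leaves
#' exactly into `group` versus its complement. A single leaf is always a clade
#' (its pendant edge); the full leaf set (or the empty set) is rejected as a
#' trivial bipartition.
#'
#' @param tree An [ape::phylo] tree.
#' @param group Character vector of leaf labels, a proper non-empty subset of
#'   the tree's leaves.
#' @return `TRUE` or `FALSE`.
#' @export
clade_check <- function(tree, group) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(group %in% tips)) {
    stop("group contains labels absent from the tree: ",
         paste(setdiff(group, tips), collapse = ", "))
  }
  if (length(group) == 0 || length(group) == length(tips)) {
    stop("group must be a proper non-empty subset of the leaves")
  }
  if (length(group) == 1 || length(group) == length(tips) - 1) {
    return(TRUE)  # pendant edge
  }
  target <- sort(match(group, tips))
  n <- length(tips)
  # leaves under each edge's child node, treating the stored tree as rooted;
  # each edge of the unrooted tree induces the bipartition {under} | {rest}
  nodes <- unique(tree$edge[, 2])
  nodes <- nodes[nodes > n]
  for (nd in nodes) {
    under <- sort(unlist(tip_descendants(tree, nd)))
    if (identical(under, target) ||
        identical(sort(setdiff(seq_len(n), under)), target)) {
      return(TRUE)
    }
  }
  FALSE
}

tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= n])
    stack <- c(stack, kids[kids > n])
  }
  out
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d An `ld_distmat` or labelled symmetric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  d <- as_distmat(d)
  lines <- c(format(nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(formatC(rownames(d)[i], width = -10),
                       formatC(d[i, ], digits = 10, format = "g")),
                     collapse = "  ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @inheritParams write_phylip
#' @export
write_distance_tsv <- function(d, path) {
  d <- as_distmat(d)
  utils::write.table(data.frame(name = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
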