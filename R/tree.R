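#' Convert an S_G matrix to a distance matrix
#'
#' Proteomic-tree distances are `d = 1 - S_G`, so identical genomes are at
#' distance 0 and genomes with no detectable similarity at distance 1.
#'
#' @param sg symmetric S_G matrix with unit diagonal.
#' @return symmetric distance matrix with zero diagonal.
#' @export
to_distance <- function(sg) {
  stopifnot(is.matrix(sg), nrow(sg) == ncol(sg))
  d <- 1 - sg
  diag(d) <- 0
  d
}

#' Build an unrooted tree with BIONJ
#'
#' Neighbor-joining agglomeration under the Q criterion with BIONJ's
#' variance-weighted reduction: at each step the pair minimizing
#' `Q_ij = (n-2) d_ij - R_i - R_j` is joined (ties broken at the lowest
#' index pair), branch lengths follow the standard NJ estimates, and the
#' reduced distances use the variance-optimal weight
#' `lambda = 1/2 + sum_k (v_jk - v_ik) / (2 (n-2) v_ij)` clamped to
#' \[0, 1\], with `v_uk = lambda v_ik + (1-lambda) v_jk -
#' lambda (1-lambda) v_ij`. Negative branch estimates are clamped to zero
#' with the deficit moved to the sibling branch so that path lengths are
#' preserved. On additive matrices the true tree is recovered exactly.
#'
#' @param dm symmetric distance matrix with dimnames (or a `dist`).
#' @return an unrooted [ape::phylo] tree (trifurcating root).
#' @export
bionj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  ids <- rownames(dm) %||% paste0("t", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n == 1) return(ape::read.tree(text = paste0("(", ids[1], ":0);")))
  if (n == 2) {
    return(ape::read.tree(text = sprintf("(%s:%.17g,%s:%.17g);",
                                         ids[1], dm[1, 2] / 2,
                                         ids[2], dm[1, 2] / 2)))
  }
  d <- unname(dm)
  v <- d
  labs <- ids
  fmt <- function(x) sprintf("%.17g", x)
  while (n > 3) {
    R <- rowSums(d)
    Q <- (n - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- d[i, j]; bi <- 0 }
    if (bj < 0) { bi <- d[i, j]; bj <- 0 }
    lam <- 0.5
    if (v[i, j] > 0) {
      k <- setdiff(seq_len(n), c(i, j))
      lam <- 0.5 + sum(v[j, k] - v[i, k]) / (2 * (n - 2) * v[i, j])
      lam <- min(1, max(0, lam))
    }
    newlab <- paste0("(", labs[i], ":", fmt(bi), ",", labs[j], ":", fmt(bj),
                     ")")
    k <- setdiff(seq_len(n), c(i, j))
    du <- lam * (d[i, k] - bi) + (1 - lam) * (d[j, k] - bj)
    vu <- lam * v[i, k] + (1 - lam) * v[j, k] - lam * (1 - lam) * v[i, j]
    d <- rbind(cbind(d[k, k, drop = FALSE], du), c(du, 0))
    v <- rbind(cbind(v[k, k, drop = FALSE], vu), c(vu, 0))
    labs <- c(labs[k], newlab)
    n <- n - 1
  }
  ba <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  bb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  bc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", labs[1], ":", fmt(max(ba, 0)),
                ",", labs[2], ":", fmt(max(bb, 0)),
                ",", labs[3], ":", fmt(max(bc, 0)), ");")
  ape::read.tree(text = txt)
}

# adjacency list (node -> data.frame(to, len)) from a phylo object
phylo_adjacency <- function(tree) {
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, len = w))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, len = w))
  }
  adj
}

# newick subtree rooted at `node`, entered from `parent` (0 for the root)
newick_from <- function(adj, labels, node, parent) {
  nb <- adj[[node]]
  nb <- nb[nb$to != parent, , drop = FALSE]
  if (!nrow(nb)) return(labels[node])
  parts <- vapply(seq_len(nrow(nb)), function(r) {
    paste0(newick_from(adj, labels, nb$to[r], node),
           ":", sprintf("%.17g", nb$len[r]))
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. The
#' edge containing the midpoint is split in two; all other branch lengths
#' are untouched.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return a rooted [ape::phylo] tree.
#' @export
midpoint_root <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 2) return(tree)
  D <- ape::dist.nodes(tree)
  tipd <- D[seq_len(ntip), seq_len(ntip), drop = FALSE]
  diam <- max(tipd)
  if (diam <= 0) {
    warning("tree has zero length; root position is arbitrary")
  }
  idx <- which(tipd == diam, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  u <- idx[1, 1]; v <- idx[1, 2]
  path <- ape::nodepath(tree, u, v)
  half <- diam / 2
  acc <- 0
  adj <- phylo_adjacency(tree)
  a <- path[1]; b <- path[2]; x <- half
  for (s in seq_len(length(path) - 1)) {
    a <- path[s]; b <- path[s + 1]
    w <- D[a, b]
    if (acc + w >= half || s == length(path) - 1) {
      x <- half - acc
      break
    }
    acc <- acc + w
  }
  w <- D[a, b]
  x <- min(max(x, 0), w)

  nn <- max(tree$edge)
  labels <- c(tree$tip.label, rep("", nn - ntip))
  root <- nn + 1L
  adj[[root]] <- data.frame(to = integer(0), len = numeric(0))
  # split edge (a, b): root sits x from a, w - x from b
  drop_edge <- function(node, other) {
    nb <- adj[[node]]
    adj[[node]] <<- nb[nb$to != other, , drop = FALSE]
  }
  drop_edge(a, b); drop_edge(b, a)
  adj[[root]] <- data.frame(to = c(a, b), len = c(x, w - x))
  adj[[a]] <- rbind(adj[[a]], data.frame(to = root, len = x))
  adj[[b]] <- rbind(adj[[b]], data.frame(to = root, len = w - x))
  txt <- paste0(newick_from(adj, labels, root, 0L), ";")
  ape::read.tree(text = txt)
}
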