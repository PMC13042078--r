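#' Convert pairwise outgroup-f3 values to distances
#'
#' Shared drift (outgroup-f3) is large for closely related pairs; its
#' inverse 1/f3 behaves as a distance and is the input to
#' neighbor-joining. The diagonal is forced to zero.
#'
#' @param f3_tbl tibble with `pop1`, `pop2`, `estimate` (> 0) for every
#'   unordered pair.
#' @return symmetric distance matrix with labels.
#' @export
f3_to_distance <- function(f3_tbl) {
  bad <- f3_tbl$estimate <= 0
  if (any(bad))
    stop("non-positive f3 for pair(s): ",
         paste(paste(f3_tbl$pop1[bad], f3_tbl$pop2[bad], sep = "-"),
               collapse = ", "))
  labels <- sort(unique(c(f3_tbl$pop1, f3_tbl$pop2)))
  D <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (k in seq_len(nrow(f3_tbl))) {
    i <- f3_tbl$pop1[k]; j <- f3_tbl$pop2[k]
    D[i, j] <- D[j, i] <- 1 / f3_tbl$estimate[k]
  }
  diag(D) <- 0
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining (Q-matrix criterion with the
#' Saitou-Nei branch-length formulas). Ties in Q are broken by
#' lexicographic order of the joined labels, so the output is a
#' deterministic function of the matrix regardless of input label order.
#'
#' @param D symmetric distance matrix with labeled rows/columns (>= 3
#'   taxa).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  stopifnot(isSymmetric(unname(D)))
  labels <- rownames(D)
  # working newick fragments per active node
  frag <- stats::setNames(labels, labels)
  active <- labels
  Dw <- D
  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(Dw)
    Q <- (m - 2) * Dw - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= abs(qmin) * 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(active[ij[1]], active[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- Dw[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dw[i, j] - li
    new_lab <- paste0("(", frag[active[i]], ":", format(li, digits = 12),
                      ",", frag[active[j]], ":", format(lj, digits = 12), ")")
    dk <- (Dw[i, ] + Dw[j, ] - Dw[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dn <- rbind(cbind(Dw[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    key <- paste0("node", m)
    rownames(Dn) <- colnames(Dn) <- c(active[keep], key)
    frag <- c(frag[active[keep]], stats::setNames(new_lab, key))
    active <- c(active[keep], key)
    Dw <- Dn
  }
  # final star join of the last three nodes
  a <- active[1]; b <- active[2]; cl <- active[3]
  la <- (Dw[a, b] + Dw[a, cl] - Dw[b, cl]) / 2
  lb <- (Dw[a, b] + Dw[b, cl] - Dw[a, cl]) / 2
  lc <- (Dw[a, cl] + Dw[b, cl] - Dw[a, b]) / 2
  nwk <- paste0("(", frag[a], ":", format(la, digits = 12), ",",
                frag[b], ":", format(lb, digits = 12), ",",
                frag[cl], ":", format(lc, digits = 12), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup and apply height transforms
#'
#' Roots at the midpoint of the outgroup's pendant edge, then (optionally)
#' replaces branch lengths by Grafen's transform — each internal node's
#' height is its number of descendant tips minus one, normalized by total
#' tips minus one so the root sits at height 1 and all tips at 0 — and
#' raises node heights to `exponent`, which expands the scale near the
#' tips while preserving topology.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup tip label to root on.
#' @param grafen apply the tip-standardizing transform (default TRUE).
#' @param exponent power applied to normalized node heights (default 0.5;
#'   1 is the identity).
#' @param attach `"midpoint"` (default) roots halfway along the pendant
#'   edge; `"tip"` attaches the root at the outgroup's node.
#' @return a rooted `phylo`; with `grafen`, node heights are in the
#'   `height` attribute (ordered as `c(tips, internal nodes)`).
#' @export
root_and_transform <- function(tree, outgroup, grafen = TRUE,
                               exponent = 0.5, attach = c("midpoint", "tip")) {
  attach <- match.arg(attach)
  if (!outgroup %in% tree$tip.label)
    stop("outgroup not in tree: ", outgroup)
  tip <- which(tree$tip.label == outgroup)
  edge_i <- which(tree$edge[, 2] == tip)
  pos <- if (attach == "midpoint") tree$edge.length[edge_i] / 2 else 0
  rooted <- phytools::reroot(tree, tip, position = pos)
  if (!grafen) return(rooted)
  nt <- length(rooted$tip.label)
  nn <- rooted$Nnode
  # descendant-tip counts per node
  ndesc <- c(rep(1, nt), rep(0, nn))
  for (e in ape::postorder(rooted)) {
    par <- rooted$edge[e, 1]; ch <- rooted$edge[e, 2]
    ndesc[par] <- ndesc[par] + ndesc[ch]
  }
  height <- pmax(ndesc - 1, 0) / (nt - 1)
  height <- height^exponent
  rooted$edge.length <- height[rooted$edge[, 1]] - height[rooted$edge[, 2]]
  attr(rooted, "height") <- height
  rooted
}

# canonical topology fingerprint: sorted list of sorted tip-label clades
topology_hash <- function(tree) {
  nt <- length(tree$tip.label)
  clades <- lapply((nt + 1):(nt + tree$Nnode), function(nd) {
    sort(tree$tip.label[unlist(phangorn_desc(tree, nd))])
  })
  paste(sort(vapply(clades, paste, "", collapse = ",")), collapse = ";")
}

phangorn_desc <- function(tree, node) {
  nt <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k)
    if (k <= nt) k else phangorn_desc(tree, k)))
}
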