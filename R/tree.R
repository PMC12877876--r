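#' Validate and normalize a mutation-annotated tree
#'
#' The observable of the model is a rooted binary tree whose branch lengths
#' are non-negative integer mutation counts (infinite-sites reconstruction).
#' This function validates an [ape::read.tree()]-style `phylo` object and
#' normalizes it:
#' \itemize{
#'   \item non-integer branch lengths are rounded to the nearest integer with
#'     a warning;
#'   \item multifurcations are resolved into consecutive binary divisions by
#'     inserting zero-mutation branches in input order (under continuous time
#'     simultaneous divisions have probability zero, so an unresolved node
#'     stands for consecutive divisions left undistinguished by mutations);
#'   \item negative or missing branch lengths are an error.
#' }
#'
#' @param tree A `phylo` object (rooted, >= 2 tips) with branch lengths equal
#'   to mutation counts.
#' @return A binary `phylo` object with integer `edge.length`, carrying class
#'   `mutation_tree`.
#' @export
as_mutation_tree <- function(tree) {
  if (inherits(tree, "mutation_tree")) return(tree)
  if (!inherits(tree, "phylo")) {
    stop("'tree' must be a 'phylo' object", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths (mutation counts required)", call. = FALSE)
  }
  if (length(tree$tip.label) < 2L) {
    stop("tree must have at least 2 tips", call. = FALSE)
  }
  len <- tree$edge.length
  if (anyNA(len)) stop("missing branch lengths", call. = FALSE)
  if (any(len < 0)) stop("negative branch lengths (mutation counts)", call. = FALSE)
  rounded <- round(len)
  if (any(abs(rounded - len) > 1e-8)) {
    warning("non-integer mutation counts rounded to nearest integer",
            call. = FALSE)
  }
  tree$edge.length <- rounded
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted", call. = FALSE)
  }
  if (!ape::is.binary(tree)) {
    n_poly <- sum(tabulate(tree$edge[, 1]) > 2L)
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
    message(sprintf(
      "resolved %d multifurcation(s) by inserting zero-mutation branches (input order)",
      n_poly
    ))
  }
  tree$edge.length <- as.numeric(round(tree$edge.length))
  class(tree) <- c("mutation_tree", "phylo")
  tree
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf(
    "Mutation-annotated tree: %d sampled cells, %d mutations in total\n",
    length(x$tip.label), sum(x$edge.length)
  ))
  invisible(x)
}

# Postorder node sequence (children before parents) for the DP kernels.
# Returns list(order = postorder node ids excluding tips and including root
# last, children = 2-column matrix of child node ids per internal node,
# edge_m = mutation count of the branch above each node, 0 for the root).
tree_dp_layout <- function(tree) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nmax <- ntip + nnode
  root <- ntip + 1L
  kids <- vector("list", nmax)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    kids[[p]] <- c(kids[[p]], edge[e, 2L])
  }
  if (any(vapply(kids[(ntip + 1L):nmax], length, 1L) != 2L)) {
    stop("tree is not binary; call as_mutation_tree() first", call. = FALSE)
  }
  edge_m <- numeric(nmax)
  edge_m[edge[, 2L]] <- tree$edge.length
  # iterative postorder: pop sequence is a preorder; writing it back to front
  # yields children-first with the root last
  ord <- integer(nnode)
  stack <- root
  k <- nnode
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ord[k] <- nd
    k <- k - 1L
    ch <- kids[[nd]]
    stack <- c(stack, ch[ch > ntip])
  }
  children <- do.call(rbind, kids[(ntip + 1L):nmax])
  list(order = ord, children = children, edge_m = edge_m,
       ntip = ntip, root = root)
}

# Mutation distance of every node from the root (path sum of edge lengths).
node_root_distance <- function(tree) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  nmax <- ntip + tree$Nnode
  dist <- numeric(nmax)
  # ape trees are not guaranteed parent-before-child in edge order; process
  # in preorder via reorder()
  re <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(re$edge))) {
    dist[re$edge[e, 2L]] <- dist[re$edge[e, 1L]] + re$edge.length[e]
  }
  dist
}

# Number of tips descending from each node.
node_tip_counts <- function(tree) {
  ntip <- length(tree$tip.label)
  nmax <- ntip + tree$Nnode
  cnt <- integer(nmax)
  cnt[seq_len(ntip)] <- 1L
  re <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(re$edge))) {
    cnt[re$edge[e, 1L]] <- cnt[re$edge[e, 1L]] + cnt[re$edge[e, 2L]]
  }
  cnt
}
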