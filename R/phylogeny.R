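# Species tree handling: the ingroup/outgroup partition at the tagged
# ancestral node, conservation classes, homoplasy cost, and the clamped
# two-state small-parsimony (minimum mutation cost) dynamic program.

#' Read a rooted species tree with a tagged ancestral node
#'
#' Parses Newick through \pkg{ape}. Branch lengths, if present, are
#' parsed and discarded: the method is parameter-free and never weights
#' branches. The ancestral node may be designated by an internal node
#' label, or by a pair of leaf names whose most recent common ancestor is
#' taken; the label wins when both are given.
#'
#' @param text Newick string (or `NULL` when `file` is given).
#' @param file path to a Newick file.
#' @param ancestor internal node label naming the tagged node.
#' @param ancestor_mrca character vector of two leaf names; their MRCA is
#'   tagged.
#' @return an object of class `species_tree`: a list with elements
#'   `phylo` (the \pkg{ape} tree) and `ancestor` (the tagged node
#'   number).
#' @export
read_species_tree <- function(text = NULL, file = NULL, ancestor = NULL,
                              ancestor_mrca = NULL) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("could not parse Newick tree", call. = FALSE)
  species_tree(phy, ancestor = ancestor, ancestor_mrca = ancestor_mrca)
}

#' Tag an ancestral node on an ape tree
#'
#' @param phy an \pkg{ape} `phylo` object (rooted).
#' @param ancestor internal node label, or an internal node number.
#' @param ancestor_mrca two leaf names whose MRCA is tagged.
#' @return an object of class `species_tree`.
#' @export
species_tree <- function(phy, ancestor = NULL, ancestor_mrca = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf names in the species tree", call. = FALSE)
  ntip <- length(phy$tip.label)
  node <- NULL
  if (!is.null(ancestor)) {
    if (is.numeric(ancestor)) {
      node <- as.integer(ancestor)
    } else {
      if (is.null(phy$node.label))
        stop("tree has no internal node labels; cannot resolve ancestor '",
             ancestor, "'", call. = FALSE)
      hit <- which(phy$node.label == ancestor)
      if (length(hit) != 1L)
        stop("ancestor label '", ancestor, "' matches ", length(hit),
             " internal nodes", call. = FALSE)
      node <- ntip + hit
    }
  } else if (!is.null(ancestor_mrca)) {
    if (length(ancestor_mrca) != 2L || !all(ancestor_mrca %in% phy$tip.label))
      stop("ancestor_mrca must name two leaves of the tree", call. = FALSE)
    node <- ape::getMRCA(phy, ancestor_mrca)
  } else {
    stop("designate the ancestral node via 'ancestor' or 'ancestor_mrca'",
         call. = FALSE)
  }
  if (node <= ntip)
    stop("the tagged ancestral node must be internal", call. = FALSE)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  if (length(kids) != 2L)
    stop("the tagged ancestral node must have exactly two children (found ",
         length(kids), ")", call. = FALSE)
  st <- structure(list(phylo = phy, ancestor = node), class = "species_tree")
  part <- species_partition(st)  # errors if O would be empty
  invisible(part)
  st
}

#' @export
print.species_tree <- function(x, ...) {
  p <- species_partition(x)
  cat("Species tree on", length(x$phylo$tip.label), "genomes;",
      "tagged ancestral node", x$ancestor, "\n")
  cat("  I1:", paste(p$I1, collapse = ", "), "\n")
  cat("  I2:", paste(p$I2, collapse = ", "), "\n")
  cat("  O :", paste(p$O, collapse = ", "), "\n")
  invisible(x)
}

node_children <- function(phy, node) phy$edge[phy$edge[, 1L] == node, 2L]

subtree_leaves <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  out <- character(0)
  for (k in node_children(phy, node)) out <- c(out, subtree_leaves(phy, k))
  out
}

#' Species partition induced by the tagged ancestral node
#'
#' The extant genomes split into the two ingroup sets `I1` and `I2` (the
#' leaf sets of the tagged node's two child subtrees, in input order) and
#' the outgroup set `O` (all remaining leaves). All three sets must be
#' nonempty.
#'
#' @param st a [species_tree()].
#' @return list with character vectors `I1`, `I2`, `O`.
#' @export
species_partition <- function(st) {
  stopifnot(inherits(st, "species_tree"))
  phy <- st$phylo
  kids <- node_children(phy, st$ancestor)
  if (length(kids) != 2L)
    stop("tagged node is not binary", call. = FALSE)
  i1 <- subtree_leaves(phy, kids[1L])
  i2 <- subtree_leaves(phy, kids[2L])
  o <- setdiff(phy$tip.label, c(i1, i2))
  if (length(o) == 0L)
    stop("outgroup set is empty: the tagged node cannot subtend every leaf",
         call. = FALSE)
  list(I1 = i1, I2 = i2, O = o)
}

check_occupancy <- function(occ, leaves) {
  if (is.null(names(occ)) || !setequal(names(occ), leaves))
    stop("occupancy must be a named logical vector over exactly the leaf set",
         call. = FALSE)
  as.logical(occ[leaves])
}

#' Conservation class of an adjacency occupancy
#'
#' An adjacency is *conserved* at the ancestral node when it is present
#' in at least two genomes belonging to at least two different sets of
#' the species partition; *fully-conserved* when present in at least one
#' genome of each of `I1`, `I2` and `O`; *partly-conserved* when
#' conserved but not fully.
#'
#' @param occ named logical vector: presence of the adjacency per genome.
#' @param part a partition from [species_partition()].
#' @return one of `"fully"`, `"partly"`, `"one_set_only"`, `"absent"`.
#' @export
conservation_class <- function(occ, part) {
  leaves <- c(part$I1, part$I2, part$O)
  p <- stats::setNames(check_occupancy(occ, leaves), leaves)
  hit <- c(any(p[part$I1]), any(p[part$I2]), any(p[part$O]))
  nsets <- sum(hit)
  if (nsets == 3L) return("fully")
  if (nsets >= 2L) return("partly")
  if (nsets == 1L) return("one_set_only")
  "absent"
}

#' Homoplasy cost of an adjacency at the tagged ancestral node
#'
#' Counts the branches around the ancestor on which the adjacency would
#' have been independently gained or lost if it were ancestral: 0 for a
#' fully-conserved adjacency, 1 for a partly-conserved one, 2 when the
#' adjacency is present in only one of the three sets, 3 when present in
#' none. Costs 2 and 3 mean the adjacency is not conserved.
#'
#' @inheritParams conservation_class
#' @return integer in 0:3.
#' @export
homoplasy_cost <- function(occ, part) {
  switch(conservation_class(occ, part),
         fully = 0L, partly = 1L, one_set_only = 2L, absent = 3L)
}

#' Minimum mutation cost of an adjacency on the species tree
#'
#' The adjacency has two states per genome, present (1) or absent (0).
#' The cost is the minimum, over all `{0,1}` labelings of the internal
#' nodes with the leaves fixed by `occ` and the tagged ancestral node
#' fixed to 1, of the number of tree edges whose endpoints carry
#' different labels. Computed by a two-state small-parsimony dynamic
#' program over the rooted tree (arbitrary out-degree; polytomies are
#' allowed outside the tagged node). Branch lengths are ignored.
#'
#' @param occ named logical vector: presence of the adjacency per genome.
#' @param st a [species_tree()].
#' @return non-negative integer.
#' @export
mutation_cost <- function(occ, st) {
  stopifnot(inherits(st, "species_tree"))
  phy <- st$phylo
  leaves <- phy$tip.label
  pres <- stats::setNames(check_occupancy(occ, leaves), leaves)
  ntip <- length(leaves)
  root <- ntip + 1L
  nnode <- ntip + phy$Nnode
  INF <- .Machine$integer.max %/% 4L
  cost <- matrix(INF, nrow = nnode, ncol = 2L)  # columns: state 0, state 1
  dp <- function(v) {
    if (v <= ntip) {
      s <- as.integer(pres[[leaves[v]]])
      cost[v, s + 1L] <<- 0L
      return(invisible())
    }
    c0 <- 0L; c1 <- 0L
    for (k in node_children(phy, v)) {
      dp(k)
      c0 <- c0 + min(cost[k, 1L], cost[k, 2L] + 1L)
      c1 <- c1 + min(cost[k, 2L], cost[k, 1L] + 1L)
    }
    cost[v, 1L] <<- c0
    cost[v, 2L] <<- c1
    if (v == st$ancestor) cost[v, 1L] <<- INF  # clamp ancestor to state 1
    invisible()
  }
  dp(root)
  as.integer(min(cost[root, ]))
}
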