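# Simulated genome evolution along a species tree under a DCJ-style
# rearrangement model (inversions, translocations, fusions, fissions),
# plus evaluation metrics.

#' Simulation configuration
#'
#' Event placement is uniform within each event type: inversions pick a
#' chromosome proportionally to its length and reverse a uniform
#' interval; translocations exchange uniform prefix/suffix pieces of two
#' chromosomes; fusions join two chromosomes in random orientations;
#' fissions split a chromosome at a uniform internal position. The same
#' configuration (including `seed`) always regenerates the identical
#' instance.
#'
#' @param n_blocks number of synteny blocks (the block universe is
#'   `1..n_blocks`).
#' @param n_chromosomes chromosomes of the root genome (blocks `1..n`
#'   split evenly, all positive, all linear).
#' @param events_per_branch rearrangement events applied on every branch
#'   (a single count, recycled over branches).
#' @param weights sampling weights of the event types, in the order
#'   inversion, translocation, fusion, fission.
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_blocks = 100L, n_chromosomes = 5L,
                              events_per_branch = 2L,
                              weights = c(inversion = 0.7,
                                          translocation = 0.15,
                                          fusion = 0.075, fission = 0.075),
                              seed = 1L) {
  if (n_blocks < 1L) stop("n_blocks must be positive", call. = FALSE)
  if (n_chromosomes < 1L || n_chromosomes > n_blocks)
    stop("need 1 <= n_chromosomes <= n_blocks", call. = FALSE)
  structure(list(n_blocks = as.integer(n_blocks),
                 n_chromosomes = as.integer(n_chromosomes),
                 events_per_branch = as.integer(events_per_branch),
                 weights = weights, seed = as.integer(seed)),
            class = "simulation_config")
}

root_genome_blocks <- function(n_blocks, n_chromosomes) {
  cuts <- floor(seq(0L, n_blocks, length.out = n_chromosomes + 1L))
  lapply(seq_len(n_chromosomes), function(i)
    seq.int(cuts[i] + 1L, cuts[i + 1L]))
}

apply_random_event <- function(chroms, weights) {
  types <- c("inversion", "translocation", "fusion", "fission")
  feasible <- c(any(lengths(chroms) >= 1L),
                length(chroms) >= 2L,
                length(chroms) >= 2L,
                any(lengths(chroms) >= 2L))
  w <- weights * feasible
  if (sum(w) == 0) return(chroms)
  type <- sample(types, 1L, prob = w)
  if (type == "inversion") {
    ci <- sample.int(length(chroms), 1L, prob = lengths(chroms))
    b <- chroms[[ci]]
    ij <- sort(sample.int(length(b), 2L, replace = TRUE))
    b[ij[1L]:ij[2L]] <- -rev(b[ij[1L]:ij[2L]])
    chroms[[ci]] <- b
  } else if (type == "translocation") {
    ci <- sample.int(length(chroms), 2L)
    a <- chroms[[ci[1L]]]; b <- chroms[[ci[2L]]]
    pa <- sample.int(length(a) + 1L, 1L) - 1L   # prefix length, 0..len
    pb <- sample.int(length(b) + 1L, 1L) - 1L
    new_a <- c(a[seq_len(pa)], b[seq_len(length(b) - pb) + pb])
    new_b <- c(b[seq_len(pb)], a[seq_len(length(a) - pa) + pa])
    if (length(new_a) == 0L || length(new_b) == 0L) return(chroms)
    chroms[[ci[1L]]] <- new_a
    chroms[[ci[2L]]] <- new_b
  } else if (type == "fusion") {
    ci <- sample.int(length(chroms), 2L)
    a <- chroms[[ci[1L]]]; b <- chroms[[ci[2L]]]
    if (sample(c(TRUE, FALSE), 1L)) a <- -rev(a)
    if (sample(c(TRUE, FALSE), 1L)) b <- -rev(b)
    chroms[[ci[1L]]] <- c(a, b)
    chroms[[ci[2L]]] <- NULL
  } else {
    ok <- which(lengths(chroms) >= 2L)
    ci <- if (length(ok) == 1L) ok else sample(ok, 1L)
    b <- chroms[[ci]]
    cut <- sample.int(length(b) - 1L, 1L)
    chroms[[ci]] <- b[seq_len(cut)]
    chroms[[length(chroms) + 1L]] <- b[seq.int(cut + 1L, length(b))]
  }
  chroms
}

#' Simulate genome evolution along a species tree
#'
#' Draws the root genome (blocks `1..n`, all positive, split evenly into
#' linear chromosomes), then walks the tree from the root applying
#' `events_per_branch` random rearrangements on every branch. Returns the
#' extant genomes at the leaves and the true genome at every internal
#' node, so reconstructions can be scored against the simulated truth.
#'
#' @param tree a [species_tree()] (or bare `phylo`; then no node is
#'   tagged and only leaf/internal genomes are returned).
#' @param cfg a [simulation_config()].
#' @return list with `leaves` (named list of [genome()]), `internal`
#'   (list of [genome()] indexed by internal node number as character),
#'   and `ancestor_truth` (the genome at the tagged node, when a
#'   [species_tree()] was given).
#' @export
simulate_genomes <- function(tree, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  phy <- if (inherits(tree, "species_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"))
  set.seed(cfg$seed)
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  state <- vector("list", ntip + phy$Nnode)
  state[[root]] <- root_genome_blocks(cfg$n_blocks, cfg$n_chromosomes)
  walk <- function(v) {
    for (k in node_children(phy, v)) {
      ch <- state[[v]]
      for (e in seq_len(cfg$events_per_branch))
        ch <- apply_random_event(ch, cfg$weights)
      state[[k]] <<- ch
      if (k > ntip) walk(k)
    }
  }
  walk(root)
  leaves <- stats::setNames(
    lapply(seq_len(ntip), function(i) genome(phy$tip.label[i], state[[i]])),
    phy$tip.label)
  internal <- stats::setNames(
    lapply(root:(ntip + phy$Nnode), function(i)
      genome(paste0("node", i), state[[i]])),
    as.character(root:(ntip + phy$Nnode)))
  out <- list(leaves = leaves, internal = internal)
  if (inherits(tree, "species_tree"))
    out$ancestor_truth <- internal[[as.character(tree$ancestor)]]
  out
}

# Neighbor table: for every block extremity, the partner extremity code,
# or 0 for a telomere.
neighbor_table <- function(x, universe) {
  nb <- integer(2L * max(universe))
  e <- adj_extremities(adjacencies_of(x))
  nb[e[, 1L]] <- e[, 2L]
  nb[e[, 2L]] <- e[, 1L]
  nb
}

#' Breakpoint distance between two block arrangements
#'
#' The number of block extremities whose neighbor (partner extremity or
#' telomere) differs between the two structures, divided by two; the
#' halving allows `.5` values when an extremity is adjacent in one
#' structure and telomeric in the other.
#'
#' @param x,y [genome()] or [car_set()] objects over the same block
#'   universe.
#' @return non-negative number (possibly half-integer).
#' @export
breakpoint_distance <- function(x, y) {
  ux <- if (inherits(x, "car_set")) car_universe(x) else genome_blocks(x)
  uy <- if (inherits(y, "car_set")) car_universe(y) else genome_blocks(y)
  if (!identical(ux, uy))
    stop("block universes differ", call. = FALSE)
  sum(neighbor_table(x, ux) != neighbor_table(y, uy)) / 2
}

#' Partition adjacencies by their supporting inputs
#'
#' Given several reconstructions (or genomes), assigns every adjacency of
#' their union to the exact subset of inputs containing it.
#'
#' @param sets named list of [car_set()] or [genome()] objects.
#' @return data frame with columns `u`, `v` and `support` (the input
#'   names containing the adjacency, joined with `+`). Cell counts sum
#'   to the size of the adjacency union.
#' @export
shared_adjacencies <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("'sets' must be a named list", call. = FALSE)
  adjs <- lapply(sets, adjacencies_of)
  uni <- as_adjacency_matrix(do.call(rbind, adjs))
  keys <- lapply(adjs, adj_keys)
  support <- vapply(adj_keys(uni), function(k)
    paste(names(sets)[vapply(keys, function(kk) k %in% kk, logical(1))],
          collapse = "+"), character(1))
  data.frame(u = uni[, 1L], v = uni[, 2L], support = unname(support))
}

#' Adjacency precision and recall against a reference
#'
#' @param cars reconstructed [car_set()] (or [genome()]).
#' @param truth reference [genome()] (or [car_set()]).
#' @return list with `precision`, `recall`, `n_reconstructed`, `n_true`,
#'   `n_shared`.
#' @export
reconstruction_accuracy <- function(cars, truth) {
  a <- adjacencies_of(cars)
  b <- adjacencies_of(truth)
  shared <- nrow(adj_intersect(a, b))
  list(precision = if (nrow(a) == 0L) NA_real_ else shared / nrow(a),
       recall = if (nrow(b) == 0L) NA_real_ else shared / nrow(b),
       n_reconstructed = nrow(a), n_true = nrow(b), n_shared = shared)
}
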