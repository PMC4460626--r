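# Randomised fixtures, built in code under fixed seeds.

# Random genome: signed permutation of 1..n split into linear (and
# optionally circular) chromosomes.
random_genome <- function(name, n, n_chrom = NULL, circular_ok = FALSE) {
  perm <- sample.int(n) * sample(c(1L, -1L), n, replace = TRUE)
  if (is.null(n_chrom)) n_chrom <- sample.int(max(1L, n %/% 3L), 1L)
  cuts <- sort(sample.int(n - 1L, min(n_chrom - 1L, n - 1L)))
  pieces <- split(perm, findInterval(seq_len(n), cuts + 1L))
  chroms <- lapply(unname(pieces), function(b)
    chromosome(b, circular = circular_ok && runif(1) < 0.3 && length(b) >= 2L))
  genome(name, chroms)
}

# Random CAR set partitioning 1..n into ordered signed groups.
random_car_set <- function(n, n_cars = NULL) {
  perm <- sample.int(n) * sample(c(1L, -1L), n, replace = TRUE)
  if (is.null(n_cars)) n_cars <- sample.int(max(1L, n %/% 2L), 1L)
  cuts <- sort(sample.int(n - 1L, min(n_cars - 1L, n - 1L)))
  car_set(unname(split(perm, findInterval(seq_len(n), cuts + 1L))))
}

# Random rooted species tree with a valid tagged internal node
# (binary at the tag, outgroup nonempty).
random_species_tree <- function(n_leaves) {
  phy <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
  phy$tip.label <- paste0("g", seq_len(n_leaves))
  ntip <- n_leaves
  root <- ntip + 1L
  cand <- setdiff(root:(ntip + phy$Nnode), root)
  cand <- cand[vapply(cand, function(v)
    sum(phy$edge[, 1L] == v) == 2L, logical(1))]
  species_tree(phy, ancestor = sample(cand, 1L))
}

# Random adjacency set over blocks 1..n (canonical, unique), with some
# deliberate extremity sharing so conflicts occur.
random_adjacencies <- function(n_adj, n_blocks) {
  rows <- lapply(seq_len(n_adj), function(i) {
    repeat {
      u <- sample.int(n_blocks, 1L) * sample(c(1L, -1L), 1L)
      v <- sample.int(n_blocks, 1L) * sample(c(1L, -1L), 1L)
      if (abs(u) != abs(v)) return(canonical_adjacency(u, v))
    }
  })
  procars:::as_adjacency_matrix(do.call(rbind, rows))
}

# Random occupancy named over tree leaves.
random_occupancy <- function(st, p = 0.5) {
  leaves <- st$phylo$tip.label
  stats::setNames(runif(length(leaves)) < p, leaves)
}
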