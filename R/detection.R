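# Detection of CAR adjacencies in extant genomes, classification of
# conserved adjacencies, and detection of DCJ-reliable adjacencies.
#
# A CAR adjacency (car_a car_b) is witnessed in an extant genome by a
# pair of consecutive segments S_a, S_b, where S_a contains only blocks
# of car_a and S_b only blocks of car_b, each satisfying one of three
# constraint tiers relative to the oriented CAR ends. Writing
# car_a = (a_1 ... a_n) in its chosen orientation:
#   tier i  : S_a is exactly the single signed block a_n;
#   tier ii : S_a has length > 1 and ends with the (unsigned) block |a_n|;
#   tier iii: S_a has length > 1 and is syntenic to a contiguous segment
#             of car_a containing |a_n| (equivalently: S_a's blocks
#             occupy a contiguous window of car_a and include |a_n|).
# The symmetric constraints govern S_b with respect to b_1. Tier i alone
# governs single-block segments, so the orientation of an isolated block
# is respected; the looser tiers tolerate micro-rearrangements inside
# longer segments at CAR ends.

# --- constraint testing -----------------------------------------------

# Does any suffix (side = "end") / prefix (side = "start") of `run`
# satisfy the constraints for the oriented CAR `ocar`?
# `car_abs` is abs() of the stored CAR (for contiguity testing).
side_satisfied <- function(run, ocar, car_abs, side) {
  n <- length(run)
  endblock <- if (side == "end") ocar[length(ocar)] else ocar[1L]
  pos <- match(abs(run), car_abs)     # positions of the run's blocks in the CAR
  target <- match(abs(endblock), car_abs)
  for (l in seq_len(n)) {
    s_idx <- if (side == "end") (n - l + 1L):n else 1:l
    if (l == 1L) {
      if (run[s_idx] == endblock) return(TRUE)       # tier i (signed)
      next
    }
    tip <- if (side == "end") run[n] else run[1L]
    if (abs(tip) == abs(endblock)) return(TRUE)      # tier ii (unsigned)
    p <- pos[s_idx]
    if (max(p) - min(p) + 1L == l && target >= min(p) && target <= max(p))
      return(TRUE)                                    # tier iii (syntenic)
  }
  FALSE
}

# Maximal runs of same-CAR blocks along one chromosome, with circular
# wrap-around merging. Returns list of list(car =, blocks =), in order,
# plus whether the run sequence is circular.
car_runs <- function(blocks, car_of, circular) {
  cars <- car_of[abs(blocks)]
  r <- rle(cars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- lapply(seq_along(r$values), function(i)
    list(car = r$values[i], blocks = blocks[starts[i]:ends[i]]))
  if (circular && length(runs) > 1L &&
      runs[[1L]]$car == runs[[length(runs)]]$car) {
    runs[[1L]]$blocks <- c(runs[[length(runs)]]$blocks, runs[[1L]]$blocks)
    runs[[length(runs)]] <- NULL
  }
  runs
}

canonical_car_pair <- function(p, q) {
  a <- c(p, q); b <- c(-q, -p)
  ka <- block_key(a); kb <- block_key(b)
  if (ka[1L] < kb[1L] || (ka[1L] == kb[1L] && ka[2L] <= kb[2L])) a else b
}

#' Detect the CAR adjacencies of a genome given the current CARs
#'
#' Scans every boundary between a maximal run of blocks of one CAR and a
#' maximal run of blocks of another CAR (including the wrap-around
#' boundary on circular chromosomes) and tests, for each orientation of
#' each CAR, whether some suffix of the left run and some prefix of the
#' right run satisfy the segment constraints. Each detected oriented CAR
#' pair carries its corresponding block adjacency `(a_n b_1)`, the
#' adjacency between the trailing block of the oriented left CAR and the
#' leading block of the oriented right CAR.
#'
#' @param g a [genome()].
#' @param cs a [car_set()] partitioning the block universe of `g`.
#' @return data frame with columns `car_a`, `car_b` (signed CAR indices,
#'   canonical writing) and `u`, `v` (the canonical block adjacency);
#'   one row per distinct CAR adjacency.
#' @export
detect_car_adjacencies <- function(g, cs) {
  stopifnot(inherits(g, "genome"), inherits(cs, "car_set"))
  cars <- unclass(cs)
  uni <- car_universe(cs)
  if (!identical(uni, genome_blocks(g)))
    stop("CAR set does not partition the block universe of genome ", g$name,
         call. = FALSE)
  car_of <- integer(max(uni))
  for (i in seq_along(cars)) car_of[abs(cars[[i]])] <- i
  car_abs <- lapply(cars, abs)

  res <- list()
  for (ch in g$chromosomes) {
    runs <- car_runs(ch$blocks, car_of, ch$circular)
    nr <- length(runs)
    if (nr < 2L) next
    bounds <- cbind(seq_len(nr - 1L), 2:nr)
    if (ch$circular) bounds <- rbind(bounds, c(nr, 1L))
    for (bi in seq_len(nrow(bounds))) {
      L <- runs[[bounds[bi, 1L]]]; R <- runs[[bounds[bi, 2L]]]
      P <- L$car; Q <- R$car
      end_ok <- c(side_satisfied(L$blocks, cars[[P]], car_abs[[P]], "end"),
                  side_satisfied(L$blocks, flip_blocks(cars[[P]]),
                                 car_abs[[P]], "end"))
      start_ok <- c(side_satisfied(R$blocks, cars[[Q]], car_abs[[Q]], "start"),
                    side_satisfied(R$blocks, flip_blocks(cars[[Q]]),
                                   car_abs[[Q]], "start"))
      for (si in 1:2) {
        if (!end_ok[si]) next
        for (ti in 1:2) {
          if (!start_ok[ti]) next
          sgn_p <- if (si == 1L) P else -P
          sgn_q <- if (ti == 1L) Q else -Q
          oc_p <- if (si == 1L) cars[[P]] else flip_blocks(cars[[P]])
          oc_q <- if (ti == 1L) cars[[Q]] else flip_blocks(cars[[Q]])
          pair <- canonical_car_pair(sgn_p, sgn_q)
          adj <- canonical_adjacency(oc_p[length(oc_p)], oc_q[1L])
          res[[length(res) + 1L]] <- c(pair, adj)
        }
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(car_a = integer(0), car_b = integer(0),
                      u = integer(0), v = integer(0)))
  m <- unique(do.call(rbind, res))
  m <- m[order(block_key(m[, 1L]), block_key(m[, 2L])), , drop = FALSE]
  data.frame(car_a = m[, 1L], car_b = m[, 2L], u = m[, 3L], v = m[, 4L])
}

#' Block adjacency corresponding to a CAR adjacency
#'
#' For the oriented pair `(car_a car_b)`, the corresponding block
#' adjacency is `(a_n b_1)`: trailing signed block of the oriented left
#' CAR against leading signed block of the oriented right CAR,
#' canonicalised.
#'
#' @param cs a [car_set()].
#' @param car_a,car_b signed CAR indices (negative = reversed
#'   orientation).
#' @return length-2 integer vector.
#' @export
block_adjacency <- function(cs, car_a, car_b) {
  stopifnot(inherits(cs, "car_set"))
  a <- unclass(cs)[[abs(car_a)]]
  if (car_a < 0L) a <- flip_blocks(a)
  b <- unclass(cs)[[abs(car_b)]]
  if (car_b < 0L) b <- flip_blocks(b)
  canonical_adjacency(a[length(a)], b[1L])
}

#' Conserved adjacencies at the ancestral node given the current CARs
#'
#' Pools [detect_car_adjacencies()] over all genomes, groups by canonical
#' block adjacency, and keeps the adjacencies whose supporting genomes
#' span at least two sets of the species partition. Adjacencies on the
#' permanent blacklist are dropped. Occupancy is boolean per genome at
#' the CAR-adjacency level.
#'
#' @param cs a [car_set()].
#' @param genomes named list of [genome()] objects.
#' @param part partition from [species_partition()].
#' @param blacklist adjacency set to exclude (permanently discarded).
#' @return an object of class `conserved_adjacencies`: list with
#'   `adjacencies` (k x 2 matrix), `conservation` (`"fully"`/`"partly"`),
#'   `homoplasy` (integer), and `occupancy` (k x genomes logical matrix).
#' @export
conserved_adjacencies <- function(cs, genomes, part, blacklist = NULL) {
  det <- lapply(genomes, detect_car_adjacencies, cs = cs)
  names(det) <- vapply(genomes, function(g) g$name, character(1))
  all_adj <- unique(do.call(rbind, lapply(det, function(d)
    cbind(d$u, d$v))))
  if (is.null(all_adj)) all_adj <- empty_adj()
  storage.mode(all_adj) <- "integer"
  all_adj <- sort_adjacencies(all_adj)
  if (!is.null(blacklist))
    all_adj <- adj_setdiff(all_adj, as_adjacency_matrix(blacklist))
  gn <- names(det)
  occ <- matrix(FALSE, nrow = nrow(all_adj), ncol = length(gn),
                dimnames = list(adj_keys(all_adj), gn))
  for (g in gn) {
    k <- paste(det[[g]]$u, det[[g]]$v)
    occ[rownames(occ) %in% k, g] <- TRUE
  }
  cls <- character(nrow(all_adj))
  for (r in seq_len(nrow(all_adj)))
    cls[r] <- conservation_class(occ[r, ], part)
  keep <- cls %in% c("fully", "partly")
  out <- list(adjacencies = all_adj[keep, , drop = FALSE],
              conservation = cls[keep],
              homoplasy = ifelse(cls[keep] == "fully", 0L, 1L),
              occupancy = occ[keep, , drop = FALSE])
  class(out) <- "conserved_adjacencies"
  out
}

#' Detect DCJ-reliable adjacencies
#'
#' A candidate adjacency `(a_n b_1)` between two free CAR ends is
#' DCJ-reliable when there is an adjacency `(x y)` inside the current
#' CARs such that some extant genome `G1` contains both block adjacencies
#' `(x b_1)` and `(a_n y)`, and `(car_a car_b)` is a CAR adjacency of
#' some extant genome `G2`, with `G1` and `G2` in two different sets of
#' the species partition. The ancestral presence of `(a_n b_1)` together
#' with `(x y)` then explains the two `G1` adjacencies by a single DCJ
#' event. Both writings of each internal adjacency are considered.
#'
#' @inheritParams conserved_adjacencies
#' @return adjacency set (k x 2 matrix) of the candidates, canonical and
#'   sorted; attribute `"support"` lists per candidate the witness
#'   genomes.
#' @export
dcj_reliable_adjacencies <- function(cs, genomes, part, blacklist = NULL) {
  stopifnot(inherits(cs, "car_set"))
  cars <- unclass(cs)
  gn <- vapply(genomes, function(g) g$name, character(1))
  names(genomes) <- gn
  set_of <- stats::setNames(rep(c("I1", "I2", "O"),
                                c(length(part$I1), length(part$I2), length(part$O))),
                            c(part$I1, part$I2, part$O))
  raw_keys <- lapply(genomes, function(g) adj_keys(adjacencies_of(g)))
  det <- lapply(genomes, detect_car_adjacencies, cs = cs)
  pair_keys <- lapply(det, function(d) paste(d$car_a, d$car_b))

  internal <- adjacencies_of(cs)      # adjacencies realised inside CARs
  bl_keys <- if (is.null(blacklist)) character(0) else
    adj_keys(as_adjacency_matrix(blacklist))

  out <- list(); support <- list()
  nc <- length(cars)
  if (nc >= 2L && nrow(internal) > 0L) {
    # both writings of every internal adjacency
    wr <- rbind(internal, cbind(-internal[, 2L], -internal[, 1L]))
    for (p in seq_len(nc)) for (sp in c(1L, -1L)) {
      oc_p <- if (sp > 0L) cars[[p]] else flip_blocks(cars[[p]])
      a_n <- oc_p[length(oc_p)]
      for (q in seq_len(nc)) for (sq in c(1L, -1L)) {
        if (q == p) next
        oc_q <- if (sq > 0L) cars[[q]] else flip_blocks(cars[[q]])
        b_1 <- oc_q[1L]
        cand <- canonical_adjacency(a_n, b_1)
        ck <- paste(cand[1L], cand[2L])
        if (ck %in% bl_keys || ck %in% names(out)) next
        pair <- canonical_car_pair(sp * p, sq * q)
        pk <- paste(pair[1L], pair[2L])
        g2 <- gn[vapply(gn, function(g) pk %in% pair_keys[[g]], logical(1))]
        if (length(g2) == 0L) next
        g1 <- character(0)
        for (w in seq_len(nrow(wr))) {
          x <- wr[w, 1L]; y <- wr[w, 2L]
          # the four cut extremities are automatically distinct: (x y) is
          # glued inside a CAR while a_n's right and b_1's left are free
          if (abs(x) == abs(b_1) || abs(y) == abs(a_n)) next
          w1 <- canonical_adjacency(x, b_1); w2 <- canonical_adjacency(a_n, y)
          k1 <- paste(w1[1L], w1[2L]); k2 <- paste(w2[1L], w2[2L])
          hits <- gn[vapply(gn, function(g)
            (k1 %in% raw_keys[[g]]) && (k2 %in% raw_keys[[g]]), logical(1))]
          g1 <- union(g1, hits)
        }
        if (length(g1) == 0L) next
        if (any(outer(set_of[g1], set_of[g2], "!="))) {
          out[[ck]] <- cand
          support[[ck]] <- list(G1 = g1, G2 = g2)
        }
      }
    }
  }
  m <- as_adjacency_matrix(out)
  attr(m, "support") <- support[adj_keys(m)]
  m
}
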