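# Independent brute-force oracles. These enumerate the definitions
# literally and stay independent of the package's algorithms.

adj_str <- function(m) if (nrow(m) == 0L) character(0) else paste(m[, 1L], m[, 2L])

# Exhaustive minimum mutation cost: enumerate all binary labelings of
# the internal nodes (ancestor clamped to 1, leaves clamped by occ) and
# count differing edges.
oracle_mutation_cost <- function(occ, st) {
  phy <- st$phylo
  ntip <- length(phy$tip.label)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  free <- setdiff(nodes, st$ancestor)
  lab <- integer(ntip + phy$Nnode)
  lab[seq_len(ntip)] <- as.integer(occ[phy$tip.label])
  lab[st$ancestor] <- 1L
  best <- Inf
  for (mask in 0:(2^length(free) - 1L)) {
    bits <- as.integer(intToBits(mask))[seq_along(free)]
    lab[free] <- bits
    cost <- sum(lab[phy$edge[, 1L]] != lab[phy$edge[, 2L]])
    best <- min(best, cost)
  }
  best
}

# Literal segment-pair enumeration of CAR adjacencies for one genome.
oracle_detect <- function(g, cs) {
  cars <- unclass(cs)
  car_of <- integer(max(car_universe(cs)))
  for (i in seq_along(cars)) car_of[abs(cars[[i]])] <- i
  ok_side <- function(S, ocar, side) {
    n <- length(S)
    tipblock <- if (side == "end") ocar[length(ocar)] else ocar[1L]
    if (n == 1L) return(S == tipblock)
    edge <- if (side == "end") S[n] else S[1L]
    if (abs(edge) == abs(tipblock)) return(TRUE)
    # syntenic to a contiguous window of the CAR containing |tipblock|
    for (i in seq_along(ocar)) for (j in i:length(ocar)) {
      w <- ocar[i:j]
      if (abs(tipblock) %in% abs(w) && setequal(abs(w), abs(S))) return(TRUE)
    }
    FALSE
  }
  found <- character(0)
  rows <- list()
  for (ch in g$chromosomes) {
    b <- ch$blocks; m <- length(b)
    seqs <- if (ch$circular) c(b, b) else b
    bounds <- if (ch$circular) seq_len(m) else seq_len(m - 1L)
    for (p in bounds) {
      for (la in 1:(m - 1L)) for (lb in 1:(m - la)) {
        ia <- (p - la + 1L):p
        ib <- (p + 1L):(p + lb)
        if (!ch$circular && (ia[1L] < 1L || ib[lb] > m)) next
        Sa <- seqs[((ia - 1L) %% m) + 1L]
        Sb <- seqs[((ib - 1L) %% m) + 1L]
        if (anyDuplicated(abs(c(Sa, Sb)))) next
        P <- unique(car_of[abs(Sa)]); Q <- unique(car_of[abs(Sb)])
        if (length(P) != 1L || length(Q) != 1L || P == Q) next
        for (sp in c(1L, -1L)) for (sq in c(1L, -1L)) {
          oa <- if (sp > 0) cars[[P]] else -rev(cars[[P]])
          ob <- if (sq > 0) cars[[Q]] else -rev(cars[[Q]])
          if (!ok_side(Sa, oa, "end") || !ok_side(Sb, ob, "start")) next
          pair <- procars:::canonical_car_pair(sp * P, sq * Q)
          adj <- canonical_adjacency(oa[length(oa)], ob[1L])
          key <- paste(pair[1L], pair[2L], adj[1L], adj[2L])
          if (!(key %in% found)) {
            found <- c(found, key)
            rows[[length(rows) + 1L]] <- c(pair, adj)
          }
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(car_a = integer(0), car_b = integer(0),
                      u = integer(0), v = integer(0)))
  m <- do.call(rbind, rows)
  data.frame(car_a = m[, 1L], car_b = m[, 2L], u = m[, 3L], v = m[, 4L])
}

# Literal set comprehension of the step a) selection partition.
oracle_step_a <- function(adj, conservation) {
  conf <- function(i, j) adjacency_conflict(adj[i, ], adj[j, ])
  k <- nrow(adj)
  idx <- seq_len(k)
  fs <- idx[conservation == "fully"]
  ps <- idx[conservation == "partly"]
  conf_any <- function(i, set) any(vapply(setdiff(set, i), conf, logical(1), i = i))
  fs_nc <- fs[!vapply(fs, conf_any, logical(1), set = fs)]
  ps_d <- ps[vapply(ps, conf_any, logical(1), set = fs_nc)]
  ps_r <- setdiff(ps, ps_d)
  ps_nc <- ps_r[!vapply(ps_r, conf_any, logical(1), set = ps_r)]
  ps_nc2 <- ps_nc[!vapply(ps_nc, conf_any, logical(1), set = fs)]
  nc <- union(fs_nc, ps_nc2)
  cc <- setdiff(setdiff(idx, ps_d), nc)
  pick <- function(s) procars:::sort_adjacencies(adj[s, , drop = FALSE])
  list(FS_NC = pick(fs_nc), PS_D = pick(ps_d), PS_NC2 = pick(ps_nc2),
       NC = pick(sort(nc)), C = pick(sort(cc)))
}

# Exhaustive optimum: maximum-size, then minimum-cost, then
# lexicographically smallest non-conflicting subset.
oracle_best_subset <- function(adj, cost) {
  k <- nrow(adj)
  if (k == 0L) return(adj)
  conf <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    conf[i, j] <- i != j && adjacency_conflict(adj[i, ], adj[j, ])
  best <- NULL
  for (mask in 0:(2^k - 1L)) {
    s <- which(as.logical(intToBits(mask))[seq_len(k)])
    if (length(s) > 1L && any(conf[s, s])) next
    cand <- list(size = length(s), cost = sum(cost[s]), s = s)
    if (is.null(best) || cand$size > best$size ||
        (cand$size == best$size && cand$cost < best$cost) ||
        (cand$size == best$size && cand$cost == best$cost &&
         lex_smaller(cand$s, best$s)))
      best <- cand
  }
  adj[best$s, , drop = FALSE]
}

lex_smaller <- function(a, b) {
  n <- min(length(a), length(b))
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

# Literal enumeration of DCJ-reliable adjacencies.
oracle_dcj_reliable <- function(cs, genomes, part, blacklist = NULL) {
  cars <- unclass(cs)
  gn <- vapply(genomes, function(g) g$name, character(1))
  names(genomes) <- gn
  set_of <- stats::setNames(
    rep(c("I1", "I2", "O"), c(length(part$I1), length(part$I2), length(part$O))),
    c(part$I1, part$I2, part$O))
  raw <- lapply(genomes, function(g) adj_str(adjacencies_of(g)))
  det <- lapply(genomes, oracle_detect, cs = cs)
  bl <- if (is.null(blacklist)) character(0) else adj_str(blacklist)
  internal <- adjacencies_of(cs)
  writings <- rbind(internal, cbind(-internal[, 2L], -internal[, 1L]))
  out <- character(0); rows <- list()
  nc <- length(cars)
  for (p in seq_len(nc)) for (sp in c(1L, -1L))
    for (q in seq_len(nc)) for (sq in c(1L, -1L)) {
      if (p == q) next
      oa <- if (sp > 0) cars[[p]] else -rev(cars[[p]])
      ob <- if (sq > 0) cars[[q]] else -rev(cars[[q]])
      a_n <- oa[length(oa)]; b_1 <- ob[1L]
      cand <- canonical_adjacency(a_n, b_1)
      ck <- paste(cand[1L], cand[2L])
      if (ck %in% bl || ck %in% out) next
      pair <- procars:::canonical_car_pair(sp * p, sq * q)
      g2 <- gn[vapply(gn, function(g)
        any(det[[g]]$car_a == pair[1L] & det[[g]]$car_b == pair[2L]),
        logical(1))]
      if (length(g2) == 0L) next
      hit <- FALSE
      for (w in seq_len(nrow(writings))) {
        x <- writings[w, 1L]; y <- writings[w, 2L]
        if (abs(x) == abs(b_1) || abs(y) == abs(a_n)) next
        k1 <- paste(canonical_adjacency(x, b_1), collapse = " ")
        k2 <- paste(canonical_adjacency(a_n, y), collapse = " ")
        g1 <- gn[vapply(gn, function(g)
          k1 %in% raw[[g]] && k2 %in% raw[[g]], logical(1))]
        if (any(vapply(g1, function(a) any(set_of[a] != set_of[g2]), logical(1))))
          hit <- TRUE
      }
      if (hit) { out <- c(out, ck); rows[[length(rows) + 1L]] <- cand }
    }
  procars:::as_adjacency_matrix(do.call(rbind, c(rows, list(procars:::empty_adj()))))
}
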