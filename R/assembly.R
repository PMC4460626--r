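# Progressive assembly: step a) structural selection among conserved
# adjacencies, step b) exact conflict resolution by mutation cost,
# step c) selection among DCJ-reliable adjacencies, and the driver loop.

#' Step a) selection partition of the conserved adjacencies
#'
#' Splits the conserved set S into fully-conserved (FS) and
#' partly-conserved (PS) adjacencies, then retains
#' `NC = FS_NC U PS_NC2`, where FS_NC are the FS adjacencies compatible
#' with all other FS adjacencies, and PS_NC2 are the PS adjacencies that
#' survive the FS_NC filter (PS_D, conflicting with FS_NC, is discarded
#' permanently), are compatible with all other survivors (PS_NC), and
#' are compatible with all of FS. The leftover set
#' `C = S - PS_D - NC` holds the conflicting adjacencies saved for a
#' possible step b): each of its members conflicts with at least one
#' other member of C and with none of NC.
#'
#' @param records a `conserved_adjacencies` object from
#'   [conserved_adjacencies()].
#' @return list of adjacency matrices: `S`, `FS`, `PS`, `FS_NC`, `FS_C`,
#'   `PS_D`, `PS_R`, `PS_NC`, `PS_NC2`, `NC`, `C`.
#' @export
select_step_a <- function(records) {
  S <- records$adjacencies
  fully <- records$conservation == "fully"
  FS <- S[fully, , drop = FALSE]
  PS <- S[!fully, , drop = FALSE]
  conflicts_with <- function(a, b) {
    # rows of a conflicting with >= 1 row of b (excluding identical rows)
    if (nrow(a) == 0L || nrow(b) == 0L) return(rep(FALSE, nrow(a)))
    ea <- adj_extremities(a); eb <- adj_extremities(b)
    ka <- adj_keys(a); kb <- adj_keys(b)
    vapply(seq_len(nrow(a)), function(i) {
      hit <- (eb[, 1L] %in% ea[i, ]) | (eb[, 2L] %in% ea[i, ])
      any(hit & kb != ka[i])
    }, logical(1))
  }
  fs_conf <- conflicts_with(FS, FS)
  FS_NC <- FS[!fs_conf, , drop = FALSE]
  FS_C <- FS[fs_conf, , drop = FALSE]
  PS_D <- PS[conflicts_with(PS, FS_NC), , drop = FALSE]
  PS_R <- adj_setdiff(PS, PS_D)
  ps_conf <- conflicts_with(PS_R, PS_R)
  PS_NC <- PS_R[!ps_conf, , drop = FALSE]
  PS_NC2 <- PS_NC[!conflicts_with(PS_NC, FS), , drop = FALSE]
  NC <- adj_union(FS_NC, PS_NC2)
  C <- adj_setdiff(adj_setdiff(S, PS_D), NC)
  list(S = S, FS = FS, PS = PS, FS_NC = FS_NC, FS_C = FS_C,
       PS_D = PS_D, PS_R = PS_R, PS_NC = PS_NC, PS_NC2 = PS_NC2,
       NC = NC, C = C)
}

# Exact maximum-cardinality, then minimum-cost, non-conflicting subset.
# Works per connected component of the conflict graph with an exhaustive
# branch-and-bound; ties broken by the lexicographically smallest list of
# canonical adjacencies. Exposed through resolve_step_b()/select_step_c().
best_nonconflicting <- function(adj, cost) {
  adj <- as_adjacency_matrix(adj)
  k <- nrow(adj)
  if (k == 0L)
    return(list(selected = empty_adj(), discarded = empty_adj()))
  cost <- as.numeric(cost)
  stopifnot(length(cost) == k)
  cm <- conflict_matrix(adj)
  comp <- integer(k); cc <- 0L
  for (i in seq_len(k)) {
    if (comp[i] != 0L) next
    cc <- cc + 1L
    stack <- i
    while (length(stack) > 0L) {
      v <- stack[[1L]]; stack <- stack[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cc
      stack <- c(stack, which(cm[v, ] & comp == 0L))
    }
  }
  chosen <- logical(k)
  for (c_id in seq_len(cc)) {
    idx <- which(comp == c_id)          # ascending = canonical order
    best <- NULL                         # list(size, cost, members)
    better <- function(size, total, members) {
      if (is.null(best)) return(TRUE)
      if (size != best$size) return(size > best$size)
      if (total != best$cost) return(total < best$cost)
      # lexicographic on the ascending member index vectors
      a <- members; b <- best$members
      n <- min(length(a), length(b))
      d <- which(a[seq_len(n)] != b[seq_len(n)])
      if (length(d) == 0L) return(FALSE)
      a[d[1L]] < b[d[1L]]
    }
    rec <- function(pos, members, total) {
      if (pos > length(idx)) {
        if (better(length(members), total, members))
          best <<- list(size = length(members), cost = total,
                        members = members)
        return(invisible())
      }
      if (!is.null(best) &&
          length(members) + (length(idx) - pos + 1L) < best$size)
        return(invisible())              # cardinality bound
      v <- idx[pos]
      if (!any(cm[v, members, drop = FALSE]))
        rec(pos + 1L, c(members, v), total + cost[v])
      rec(pos + 1L, members, total)
    }
    rec(1L, integer(0), 0)
    chosen[best$members] <- TRUE
  }
  list(selected = adj[chosen, , drop = FALSE],
       discarded = adj[!chosen, , drop = FALSE])
}

#' Step b) exact resolution of a conflicting adjacency set
#'
#' Finds a non-conflicting subset of `C` of maximum size and, among
#' those, of minimum total cost (the per-adjacency minimum mutation cost
#' from [mutation_cost()]). Ties are broken by the lexicographically
#' smallest canonical adjacency list, making runs reproducible. The
#' adjacencies not selected are discarded permanently.
#'
#' @param C adjacency set (matrix).
#' @param cost numeric vector of costs aligned with the canonical sorted
#'   rows of `C`.
#' @return list with adjacency matrices `selected` and `discarded`.
#' @export
resolve_step_b <- function(C, cost) {
  C2 <- as_adjacency_matrix(C)
  if (nrow(C2) != length(cost))
    stop("one cost per adjacency is required", call. = FALSE)
  # align costs with the canonicalised, sorted rows
  if (!is.matrix(C)) C <- as_adjacency_matrix(C)
  key_in <- adj_keys(t(apply(C, 1L, canonical_adjacency)))
  cost <- cost[match(adj_keys(C2), key_in)]
  best_nonconflicting(C2, cost)
}

#' Step c) selection among DCJ-reliable adjacencies
#'
#' Maximum-cardinality non-conflicting subset, lexicographic tie-break;
#' the rest is discarded permanently.
#'
#' @param candidates adjacency set from [dcj_reliable_adjacencies()].
#' @return list with adjacency matrices `selected` and `discarded`.
#' @export
select_step_c <- function(candidates) {
  m <- as_adjacency_matrix(candidates)
  best_nonconflicting(m, rep(0, nrow(m)))
}

# --- driver ------------------------------------------------------------

new_report <- function(step_index, step_kind, cs, added, discarded) {
  sizes <- lengths(unclass(cs))
  list(step_index = step_index, step_kind = step_kind,
       n_cars_after = length(cs),
       car_size_range = c(min(sizes), max(sizes)),
       n_added = nrow(added), added = added, discarded = discarded)
}

#' Run the progressive CAR reconstruction
#'
#' Starts from one single-block CAR per block and iterates: detect the
#' conserved CAR adjacencies and apply the step a) selection; if it
#' retains adjacencies, concatenate and start over. When step a) retains
#' nothing but leaves a conflicting set C, resolve C exactly by minimum
#' mutation cost (step b). When C is empty too, detect DCJ-reliable
#' adjacencies and add a maximum non-conflicting subset (step c). The
#' loop stops when no step can add an adjacency. Adjacencies discarded by
#' any step (and adjacencies whose addition would close a circular CAR)
#' are blacklisted permanently. Only productive steps are numbered, after
#' an initial step 0 row.
#'
#' @param genomes named list of [genome()] objects over one block
#'   universe.
#' @param tree a [species_tree()] whose leaf labels match the genome
#'   names.
#' @param verbose print one line per productive step.
#' @return list with elements `cars` (the final [car_set()]), `steps`
#'   (list of per-step records: index, kind, CAR count, size range,
#'   added/discarded adjacency matrices) and `discarded` (data frame of
#'   permanently discarded adjacencies with step and reason).
#' @export
run_procars <- function(genomes, tree, verbose = FALSE) {
  stopifnot(inherits(tree, "species_tree"))
  gn <- vapply(genomes, function(g) g$name, character(1))
  names(genomes) <- gn
  if (!setequal(gn, tree$phylo$tip.label))
    stop("genome names and tree leaf labels differ: ",
         paste(symdiff <- union(setdiff(gn, tree$phylo$tip.label),
                                setdiff(tree$phylo$tip.label, gn)),
               collapse = ", "), call. = FALSE)
  uni <- validate_genomes(genomes)
  part <- species_partition(tree)

  cars <- initial_cars(uni)
  blacklist <- empty_adj()
  disc_log <- data.frame(u = integer(0), v = integer(0),
                         step = integer(0), reason = character(0))
  note_discard <- function(m, step, reason) {
    if (nrow(m) == 0L) return(invisible())
    blacklist <<- adj_union(blacklist, m)
    disc_log <<- rbind(disc_log,
                       data.frame(u = m[, 1L], v = m[, 2L],
                                  step = step, reason = reason))
    invisible()
  }

  steps <- list(new_report(0L, "init", cars, empty_adj(), empty_adj()))
  step_no <- 0L
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 4L * length(uni) + 10L)
      stop("internal error: assembly loop failed to terminate", call. = FALSE)
    rec <- conserved_adjacencies(cars, genomes, part, blacklist)
    sel <- select_step_a(rec)
    note_discard(sel$PS_D, step_no + 1L, "PS_D")
    if (nrow(sel$NC) > 0L) {
      cars <- concatenate_cars(cars, sel$NC)
      note_discard(attr(cars, "cycle_deferred"), step_no + 1L, "cycle-deferred")
      added <- attr(cars, "added")
      if (nrow(added) > 0L) {
        step_no <- step_no + 1L
        steps[[length(steps) + 1L]] <-
          new_report(step_no, "a", cars, added, empty_adj())
        if (verbose)
          message(sprintf("step %d (a): +%d adjacencies, %d CARs",
                          step_no, nrow(added), length(cars)))
      }
      next
    }
    if (nrow(sel$C) > 0L) {
      occ <- rec$occupancy[rownames(rec$occupancy) %in% adj_keys(sel$C), ,
                           drop = FALSE]
      costs <- vapply(adj_keys(sel$C), function(k)
        mutation_cost(occ[k, ], tree), integer(1))
      res <- resolve_step_b(sel$C, costs)
      note_discard(res$discarded, step_no + 1L, "step-b")
      cars <- concatenate_cars(cars, res$selected)
      note_discard(attr(cars, "cycle_deferred"), step_no + 1L, "cycle-deferred")
      added <- attr(cars, "added")
      if (nrow(added) > 0L) {
        step_no <- step_no + 1L
        steps[[length(steps) + 1L]] <-
          new_report(step_no, "b", cars, added, res$discarded)
        if (verbose)
          message(sprintf("step %d (b): +%d adjacencies, %d CARs",
                          step_no, nrow(added), length(cars)))
      }
      next
    }
    cand <- dcj_reliable_adjacencies(cars, genomes, part, blacklist)
    if (nrow(cand) == 0L) break
    # every DCJ-reliable adjacency has homoplasy cost exactly 2 here
    for (r in seq_len(nrow(cand))) {
      dets <- vapply(genomes, function(g) {
        d <- detect_car_adjacencies(g, cars)
        paste(cand[r, 1L], cand[r, 2L]) %in% paste(d$u, d$v)
      }, logical(1))
      stopifnot(homoplasy_cost(stats::setNames(dets, gn), part) == 2L)
    }
    res <- select_step_c(cand)
    note_discard(res$discarded, step_no + 1L, "step-c")
    cars <- concatenate_cars(cars, res$selected)
    note_discard(attr(cars, "cycle_deferred"), step_no + 1L, "cycle-deferred")
    added <- attr(cars, "added")
    if (nrow(added) > 0L) {
      step_no <- step_no + 1L
      steps[[length(steps) + 1L]] <-
        new_report(step_no, "c", cars, added, res$discarded)
      if (verbose)
        message(sprintf("step %d (c): +%d adjacencies, %d CARs",
                        step_no, nrow(added), length(cars)))
    }
  }
  attr(cars, "added") <- NULL
  attr(cars, "cycle_deferred") <- NULL
  list(cars = cars, steps = steps, discarded = disc_log)
}
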