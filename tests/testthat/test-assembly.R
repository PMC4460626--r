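# Step a/b/c selection and the progressive driver.

test_that("conflict is sharing a block extremity", {
  expect_true(adjacency_conflict(c(7, 8), c(7, -8)))   # head of 7 twice
  expect_false(adjacency_conflict(c(1, 2), c(1, 2)))   # equal, not conflicting
  expect_false(adjacency_conflict(c(1, 2), c(3, 4)))
  # (1 2) uses the tail of 2, (2 3) its head: compatible
  expect_false(adjacency_conflict(c(1, 2), c(2, 3)))
  expect_true(adjacency_conflict(c(1, 2), c(-2, 3)))   # tail of 2 twice
})

test_that("step a) retains fully-conserved first, then compatible partly", {
  mk <- function(adj, cls) {
    m <- procars:::as_adjacency_matrix(adj)
    structure(list(adjacencies = m, conservation = cls,
                   homoplasy = ifelse(cls == "fully", 0L, 1L),
                   occupancy = NULL), class = "conserved_adjacencies")
  }
  # no conflicts anywhere: everything is retained
  sel <- select_step_a(mk(rbind(c(1, 2), c(3, 4)), c("fully", "partly")))
  expect_equal(adj_str(sel$NC), c("1 2", "3 4"))
  expect_equal(nrow(sel$C), 0L)
  expect_equal(nrow(sel$PS_D), 0L)
  # two conflicting fully-conserved adjacencies end in C
  sel <- select_step_a(mk(rbind(c(7, 8), c(7, -8)), c("fully", "fully")))
  expect_equal(nrow(sel$FS_NC), 0L)
  expect_equal(nrow(sel$NC), 0L)
  expect_equal(adj_str(sel$C), adj_str(procars:::as_adjacency_matrix(
    rbind(c(7, 8), c(7, -8)))))
  # a partly adjacency conflicting with retained FS_NC is discarded
  sel <- select_step_a(mk(rbind(c(1, 2), c(1, -2)), c("fully", "partly")))
  expect_equal(adj_str(sel$NC), "1 2")
  expect_equal(adj_str(sel$PS_D), adj_str(procars:::as_adjacency_matrix(rbind(c(1, -2)))))
  # a partly adjacency conflicting only with FS_C is excluded from NC but kept in C
  sel <- select_step_a(mk(rbind(c(1, 2), c(1, -2), c(3, 2)),
                          c("fully", "fully", "partly")))
  expect_equal(nrow(sel$NC), 0L)
  expect_equal(nrow(sel$PS_D), 0L)
  expect_equal(nrow(sel$C), 3L)
})

test_that("step a) set algebra matches the literal comprehension oracle", {
  set.seed(141)
  for (i in 1:30) {
    adj <- random_adjacencies(sample(4:10, 1L), 6L)
    cls <- sample(c("fully", "partly"), nrow(adj), replace = TRUE)
    rec <- structure(list(adjacencies = adj, conservation = cls,
                          homoplasy = ifelse(cls == "fully", 0L, 1L)),
                     class = "conserved_adjacencies")
    sel <- select_step_a(rec)
    ora <- oracle_step_a(adj, cls)
    for (nm in names(ora))
      expect_equal(adj_str(sel[[nm]]), adj_str(ora[[nm]]), label = nm)
    # structural invariants
    expect_equal(adj_str(procars:::adj_union(sel$FS, sel$PS)), adj_str(sel$S))
    expect_equal(nrow(procars:::adj_intersect(sel$FS, sel$PS)), 0L)
    expect_equal(adj_str(procars:::adj_union(sel$FS_NC, sel$PS_NC2)),
                 adj_str(sel$NC))
    expect_equal(adj_str(sel$C),
                 adj_str(procars:::adj_setdiff(
                   procars:::adj_setdiff(sel$S, sel$PS_D), sel$NC)))
    if (nrow(sel$NC) > 1L)
      expect_false(any(procars:::conflict_matrix(sel$NC)))
    # every member of C conflicts with another member of C and none of NC
    if (nrow(sel$C) > 0L) {
      cmC <- procars:::conflict_matrix(sel$C)
      expect_true(all(rowSums(cmC) >= 1L))
      for (r in seq_len(nrow(sel$C)))
        for (s in seq_len(nrow(sel$NC)))
          expect_false(adjacency_conflict(sel$C[r, ], sel$NC[s, ]))
    }
  }
})

test_that("step b) picks the maximum subset of minimum mutation cost", {
  # the conflicting pair costs 3 and 2: the cheaper one wins
  C <- rbind(c(7, 8), c(7, -8))
  res <- resolve_step_b(C, c(3, 2))
  expect_equal(adj_str(res$selected),
               paste(canonical_adjacency(7, -8), collapse = " "))
  expect_equal(adj_str(res$discarded), "7 8")
  # two independent conflict pairs: one winner each
  C <- procars:::as_adjacency_matrix(rbind(c(1, 2), c(1, -2), c(3, 4), c(3, -4)))
  res <- resolve_step_b(C, c(1, 2, 5, 1))
  expect_equal(nrow(res$selected), 2L)
  expect_equal(adj_str(res$selected), c("1 2", "3 -4"))
})

test_that("steps b) and c) agree with exhaustive subset enumeration", {
  set.seed(151)
  for (i in 1:30) {
    adj <- random_adjacencies(sample(4:9, 1L), 5L)
    cost <- sample(0:3, nrow(adj), replace = TRUE)
    res <- resolve_step_b(adj, cost)
    ora <- oracle_best_subset(adj, cost)
    expect_equal(adj_str(res$selected), adj_str(ora))
    expect_equal(adj_str(res$discarded),
                 adj_str(procars:::adj_setdiff(adj, ora)))
    resc <- select_step_c(adj)
    orac <- oracle_best_subset(adj, rep(0, nrow(adj)))
    expect_equal(adj_str(resc$selected), adj_str(orac))
  }
})

test_that("tied singleton conflicts resolve to the lexicographically smaller", {
  res <- select_step_c(rbind(c(1, 2), c(1, 3)))
  expect_equal(nrow(res$selected), 1L)
  expect_equal(adj_str(res$selected), "1 2")
})

test_that("identical one-chromosome genomes collapse to a single CAR in one step", {
  st <- read_species_tree("(A,(B,(C,(D,E)ANC)));", ancestor = "ANC")
  gs <- lapply(c("A", "B", "C", "D", "E"), function(nm)
    genome(nm, list(c(1, -3, 2, 5, 4))))
  run <- run_procars(gs, st)
  expect_equal(length(run$cars), 1L)
  # a CAR equals the shared chromosome up to a flip
  got <- run$cars[[1]]
  expect_true(identical(got, c(1L, -3L, 2L, 5L, 4L)) ||
                identical(got, -rev(c(1L, -3L, 2L, 5L, 4L))))
  productive <- Filter(function(s) s$step_index > 0L, run$steps)
  expect_equal(length(productive), 1L)
  expect_equal(productive[[1]]$step_kind, "a")
  expect_equal(productive[[1]]$n_added, 4L)
})

test_that("the five-genome instance assembles with a step b resolving (7 8)/(7 -8)", {
  ex <- five_genome_example()
  run <- run_procars(ex$genomes, ex$tree)
  kinds <- vapply(run$steps, function(s) s$step_kind, character(1))
  expect_true("b" %in% kinds)
  badd <- run$steps[[which(kinds == "b")[1]]]$added
  expect_true("7 -8" %in% adj_str(badd))
  expect_true(any(run$discarded$u == 7 & run$discarded$v == 8 &
                    run$discarded$reason == "step-b"))
  # the winning adjacency sits inside a final CAR, the loser nowhere
  final_adj <- adj_str(adjacencies_of(run$cars))
  expect_true("7 -8" %in% final_adj)
  expect_false("7 8" %in% final_adj)
})

test_that("driver invariants hold across simulated runs", {
  set.seed(161)
  for (i in 1:5) {
    st <- random_species_tree(6L)
    cfg <- simulation_config(n_blocks = 30L, n_chromosomes = 3L,
                             events_per_branch = 1L, seed = 200L + i)
    sim <- simulate_genomes(st, cfg)
    run <- run_procars(sim$leaves, st)
    # block partition conserved
    expect_equal(procars:::car_universe(run$cars), 1:30)
    # CAR-internal adjacencies pairwise compatible
    internal <- adjacencies_of(run$cars)
    if (nrow(internal) > 1L)
      expect_false(any(procars:::conflict_matrix(internal)))
    # discarded adjacencies never end up inside CARs
    if (nrow(internal) > 0L && nrow(run$discarded) > 0L) {
      dk <- paste(run$discarded$u, run$discarded$v)
      expect_equal(length(intersect(dk, adj_str(internal))), 0L)
    }
    # productive steps strictly decrease the CAR count
    ncars <- vapply(run$steps, function(s) s$n_cars_after, integer(1))
    expect_true(all(diff(ncars) < 0L))
  }
})

test_that("previously conserved adjacencies persist, conflict, or recur", {
  # Proposition-2 regression across the driver's iterations
  set.seed(171)
  for (i in 1:3) {
    st <- random_species_tree(5L)
    cfg <- simulation_config(n_blocks = 20L, n_chromosomes = 2L,
                             events_per_branch = 1L, seed = 300L + i)
    sim <- simulate_genomes(st, cfg)
    part <- species_partition(st)
    cars <- initial_cars(1:20)
    prev_S <- NULL
    for (iter in 1:6) {
      rec <- conserved_adjacencies(cars, sim$leaves, part)
      S <- rec$adjacencies
      if (!is.null(prev_S)) {
        internal <- adjacencies_of(cars)
        ik <- adj_str(internal)
        for (r in seq_len(nrow(prev_S))) {
          a <- prev_S[r, ]
          in_cars <- paste(a[1], a[2]) %in% ik
          confl <- nrow(internal) > 0L &&
            any(vapply(seq_len(nrow(internal)), function(j)
              adjacency_conflict(a, internal[j, ]), logical(1)))
          redetected <- paste(a[1], a[2]) %in% adj_str(S)
          expect_true(in_cars || confl || redetected)
        }
      }
      prev_S <- S
      sel <- select_step_a(rec)
      if (nrow(sel$NC) == 0L) break
      cars <- concatenate_cars(cars, sel$NC)
    }
  }
})
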