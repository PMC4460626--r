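# CAR-adjacency detection, conserved classification, DCJ-reliable
# adjacencies.

test_that("the three-CAR worked instance yields exactly three CAR adjacencies", {
  ex <- car_adjacency_example()
  det <- detect_car_adjacencies(ex$genome, ex$cars)
  expect_equal(nrow(det), 3L)
  got <- sort(paste(det$u, det$v))
  want <- sort(vapply(list(c(3, 4), c(7, -10), c(10, 1)), function(a)
    paste(canonical_adjacency(a), collapse = " "), character(1)))
  expect_equal(got, want)
  # block adjacency of an oriented CAR pair, and its flip symmetry
  expect_equal(block_adjacency(ex$cars, 2, -3), canonical_adjacency(7, -10))
  expect_equal(block_adjacency(ex$cars, 3, -2), canonical_adjacency(7, -10))
  expect_equal(block_adjacency(ex$cars, 3, 1), canonical_adjacency(10, 1))
})

test_that("with singleton CARs detection returns the block adjacencies", {
  set.seed(91)
  for (i in 1:10) {
    g <- random_genome("g", 9L, circular_ok = TRUE)
    cs <- initial_cars(1:9)
    det <- detect_car_adjacencies(g, cs)
    got <- procars:::as_adjacency_matrix(cbind(det$u, det$v))
    expect_identical(got, adjacencies_of(g))
  }
})

test_that("detection agrees with the literal segment-pair oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(6:12, 1L)
    g <- random_genome("g", n, circular_ok = i %% 3 == 0)
    cs <- random_car_set(n)
    det <- detect_car_adjacencies(g, cs)
    ora <- oracle_detect(g, cs)
    key <- function(d) sort(paste(d$car_a, d$car_b, d$u, d$v))
    expect_equal(key(det), key(ora))
  }
})

test_that("a genome joins a signed CAR end to at most two partner CARs", {
  # both orientations of one partner can be witnessed at a boundary, so
  # the bound holds for distinct partner CARs per signed CAR end
  set.seed(111)
  for (i in 1:20) {
    n <- sample(8:14, 1L)
    g <- random_genome("g", n)
    cs <- random_car_set(n)
    det <- detect_car_adjacencies(g, cs)
    if (nrow(det) == 0L) next
    # both writings of each detected pair: (car_a car_b) and (-car_b -car_a)
    ends <- c(det$car_a, -det$car_b)
    partners <- abs(c(det$car_b, det$car_a))
    npart <- tapply(partners, ends, function(x) length(unique(x)))
    expect_true(all(npart <= 2L))
  }
})

test_that("conserved classification spans at least two partition sets", {
  ex <- five_genome_example()
  rec <- conserved_adjacencies(initial_cars(1:8), ex$genomes, ex$partition)
  keys <- adj_str(rec$adjacencies)
  expect_true(paste(canonical_adjacency(6, 7), collapse = " ") %in% keys)
  expect_equal(rec$conservation[match(paste(canonical_adjacency(6, 7),
                                            collapse = " "), keys)], "fully")
  for (a in list(c(1, 2), c(3, -5), c(7, 8), c(7, -8)))
    expect_true(paste(canonical_adjacency(a), collapse = " ") %in% keys)
  # (3 4) is shared by A, B, C only -- one set, hence not conserved
  expect_false(paste(canonical_adjacency(3, 4), collapse = " ") %in% keys)
  # homoplasy consistent with class
  expect_equal(rec$homoplasy, ifelse(rec$conservation == "fully", 0L, 1L))
  # blacklisting removes an adjacency from the records
  rec2 <- conserved_adjacencies(initial_cars(1:8), ex$genomes, ex$partition,
                                blacklist = rbind(c(1, 2)))
  expect_false(paste(canonical_adjacency(1, 2), collapse = " ") %in%
                 adj_str(rec2$adjacencies))
})

test_that("classification recomposes from per-genome detection", {
  set.seed(121)
  for (i in 1:10) {
    n <- 10L
    st <- random_species_tree(5L)
    part <- species_partition(st)
    gs <- lapply(st$phylo$tip.label, random_genome, n = n)
    names(gs) <- st$phylo$tip.label
    cs <- random_car_set(n)
    rec <- conserved_adjacencies(cs, gs, part)
    dets <- lapply(gs, function(g) {
      d <- detect_car_adjacencies(g, cs)
      paste(d$u, d$v)
    })
    pool <- unique(unlist(dets))
    for (k in pool) {
      occ <- stats::setNames(vapply(dets, function(d) k %in% d, logical(1)),
                             names(gs))
      expect_equal(k %in% adj_str(rec$adjacencies),
                   conservation_class(occ, part) %in% c("fully", "partly"))
    }
    if (nrow(rec$occupancy) > 0L)
      for (g in names(gs))
        expect_equal(unname(rec$occupancy[, g]),
                     adj_str(rec$adjacencies) %in% dets[[g]])
  }
})

test_that("a DCJ-reliable adjacency needs witnesses across two sets", {
  # CARs (11 1), (2 12), (13 14); G1 (in I2) holds (1 14) and (13 2);
  # G2 (in O) shows the CAR adjacency joining (11 1) to (2 12).
  cs <- car_set(list(c(11, 1), c(2, 12), c(13, 14)))
  st <- read_species_tree("(G2,(G3,(G0,G1)ANC));", ancestor = "ANC")
  part <- species_partition(st)
  g1 <- genome("G1", list(c(11, 1, 14, -12, -2, -13)))
  g2 <- genome("G2", list(c(11, 1, 2, 12), c(13, 14)))
  g0 <- genome("G0", list(c(11, 1), c(2, 12), c(13, 14)))
  g3 <- genome("G3", list(c(11, 1), c(2, 12), c(13, 14)))
  got <- dcj_reliable_adjacencies(cs, list(g0, g1, g2, g3), part,
                                  blacklist = rbind(c(1, 2)))
  expect_false(paste(canonical_adjacency(1, 2), collapse = " ") %in% adj_str(got))
  got2 <- dcj_reliable_adjacencies(cs, list(g0, g1, g2, g3), part)
  expect_true(paste(canonical_adjacency(1, 2), collapse = " ") %in% adj_str(got2))
  # no genome holding both witness adjacencies -> not reliable
  g1b <- genome("G1", list(c(11, 1, 14, -12, 2, 13)))  # breaks (13 2)
  got3 <- dcj_reliable_adjacencies(cs, list(g0, g1b, g2, g3), part)
  expect_false(paste(canonical_adjacency(1, 2), collapse = " ") %in% adj_str(got3))
})

test_that("DCJ-reliable detection matches the enumeration oracle", {
  set.seed(131)
  for (i in 1:15) {
    n <- sample(8:12, 1L)
    st <- random_species_tree(4L)
    part <- species_partition(st)
    gs <- lapply(st$phylo$tip.label, random_genome, n = n)
    cs <- random_car_set(n, n_cars = sample(3:5, 1L))
    got <- dcj_reliable_adjacencies(cs, gs, part)
    ora <- oracle_dcj_reliable(cs, gs, part)
    expect_equal(adj_str(got), adj_str(ora))
  }
})
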