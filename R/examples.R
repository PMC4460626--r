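# Bundled worked examples.

#' The five-genome textbook instance
#'
#' A small synthetic instance over eight blocks (`a..h` = `1..8`) and
#' five genomes `A`..`E`, with the ancestral node tagged as the parent of
#' `D` and `E` (so `I1 = {D}`, `I2 = {E}`, `O = {A, B, C}`). It exhibits
#' one fully-conserved adjacency, `(6 7)`; the conflicting conserved pair
#' `(7 8)` / `(7 -8)` with mutation costs 3 and 2; adjacencies of every
#' homoplasy cost, e.g. `(6 7)` cost 0, `(1 2)` cost 1, `(1 -2)` cost 2,
#' `(1 3)` cost 3; and the syntenic segments `{8 -7 -6 4}` of `D` and
#' `{-4 6 7 8}` of `E`. The instance is reconstructed (synthetic), not
#' measured data.
#'
#' @return list with `genomes` (named list of [genome()]), `tree` (a
#'   [species_tree()] tagged at the `D`/`E` ancestor), and `partition`.
#' @export
five_genome_example <- function() {
  gf <- system.file("extdata", "five_genomes_synthetic.txt",
                    package = "procars", mustWork = TRUE)
  tf <- system.file("extdata", "five_genomes_synthetic.nwk",
                    package = "procars", mustWork = TRUE)
  genomes <- read_block_orders(gf)
  tree <- read_species_tree(file = tf, ancestor = "ANC")
  list(genomes = genomes, tree = tree, partition = species_partition(tree))
}

#' The three-CAR detection example
#'
#' Ten blocks (`a..j` = `1..10`) arranged in three CARs,
#' `car_1 = (1 2 3)`, `car_2 = (4 5 6 7)`, `car_3 = (8 9 10)`, and one
#' genome `G = (2 3 -4 6 | 5 -7 9 10 1 -8)` exhibiting exactly three CAR
#' adjacencies, `(car_1 car_2)`, `(car_2 -car_3)` and `(car_3 car_1)`,
#' whose block adjacencies are `(3 4)`, `(7 -10)` and `(10 1)`.
#'
#' @return list with `cars` (a [car_set()]) and `genome` (a [genome()]).
#' @export
car_adjacency_example <- function() {
  list(cars = car_set(list(1:3, 4:7, 8:10)),
       genome = genome("G", list(c(2L, 3L, -4L, 6L),
                                 c(5L, -7L, 9L, 10L, 1L, -8L))))
}
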