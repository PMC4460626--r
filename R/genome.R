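# Genomes, chromosomes, CARs.

#' Construct a chromosome
#'
#' @param blocks integer vector of signed blocks; no block id may occur
#'   twice within the chromosome.
#' @param circular logical; `TRUE` for a circular chromosome.
#' @return an object of class `chromosome`.
#' @export
chromosome <- function(blocks, circular = FALSE) {
  blocks <- check_signed_blocks(blocks)
  if (length(blocks) == 0L) stop("chromosome must be nonempty", call. = FALSE)
  if (anyDuplicated(abs(blocks)))
    stop("duplicated block id within a chromosome: ",
         paste(unique(abs(blocks)[duplicated(abs(blocks))]), collapse = ", "),
         call. = FALSE)
  structure(list(blocks = as.integer(blocks), circular = isTRUE(circular)),
            class = "chromosome")
}

#' Construct a genome
#'
#' A genome is a named set of linear and/or circular chromosomes over a
#' block universe in which every block occurs exactly once.
#'
#' @param name genome name (matches a leaf of the species tree).
#' @param chromosomes a list of [chromosome()] objects, or plain integer
#'   vectors (taken as linear chromosomes).
#' @return an object of class `genome`.
#' @export
genome <- function(name, chromosomes) {
  if (!is.list(chromosomes) || inherits(chromosomes, "chromosome"))
    chromosomes <- list(chromosomes)
  chromosomes <- lapply(chromosomes, function(ch) {
    if (inherits(ch, "chromosome")) ch else chromosome(ch)
  })
  ids <- unlist(lapply(chromosomes, function(ch) abs(ch$blocks)))
  if (anyDuplicated(ids))
    stop("genome ", name, ": block id occurs on more than one chromosome: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(name = as.character(name), chromosomes = chromosomes),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(">", x$name, "\n")
  for (ch in x$chromosomes)
    cat(" ", paste(ch$blocks, collapse = " "),
        if (ch$circular) "@" else "$", "\n")
  invisible(x)
}

genome_blocks <- function(g) {
  sort(unlist(lapply(g$chromosomes, function(ch) abs(ch$blocks))))
}

#' Validate a set of genomes over a shared block universe
#'
#' @param genomes list of [genome()] objects.
#' @return invisibly, the sorted common block universe.
#' @export
validate_genomes <- function(genomes) {
  if (length(genomes) < 1L) stop("no genomes", call. = FALSE)
  uni <- genome_blocks(genomes[[1L]])
  for (g in genomes) {
    b <- genome_blocks(g)
    if (!identical(b, uni))
      stop("genome ", g$name, " does not share the block universe of genome ",
           genomes[[1L]]$name, call. = FALSE)
  }
  invisible(uni)
}

#' Adjacencies of a genome, chromosome or CAR set
#'
#' One adjacency per pair of consecutive signed blocks within each
#' chromosome; circular chromosomes additionally contribute the
#' wrap-around pair. Telomeres are not adjacency partners, so a
#' single-block linear chromosome has no adjacency.
#'
#' @param x a [genome()], a [chromosome()], a [car_set()], or a plain
#'   integer vector (read as one linear chromosome).
#' @return an adjacency set: a `k x 2` integer matrix of canonical
#'   adjacencies, sorted and unique.
#' @examples
#' adjacencies_of(genome("A", list(1:4)))
#' @export
adjacencies_of <- function(x) {
  chroms <- as_block_sequences(x)
  out <- list()
  for (ch in chroms) {
    b <- ch$blocks
    n <- length(b)
    if (n >= 2L) out[[length(out) + 1L]] <- cbind(b[-n], b[-1L])
    if (isTRUE(ch$circular) && n >= 2L)
      out[[length(out) + 1L]] <- cbind(b[n], b[1L])
  }
  as_adjacency_matrix(do.call(rbind, c(out, list(empty_adj()))))
}

# Normalize the accepted containers to a list of list(blocks, circular).
as_block_sequences <- function(x) {
  if (inherits(x, "genome")) return(x$chromosomes)
  if (inherits(x, "chromosome")) return(list(x))
  if (inherits(x, "car_set"))
    return(lapply(unclass(x), function(b) list(blocks = b, circular = FALSE)))
  if (is.numeric(x)) return(list(list(blocks = as.integer(x), circular = FALSE)))
  if (is.list(x))
    return(lapply(x, function(ch) {
      if (inherits(ch, "chromosome")) ch
      else list(blocks = as.integer(ch), circular = FALSE)
    }))
  stop("cannot interpret object as block sequences", call. = FALSE)
}

#' Are two segments syntenic?
#'
#' Two segments are syntenic when they contain the same set of blocks;
#' order and orientation are ignored.
#'
#' @param s1,s2 integer vectors of signed blocks.
#' @return logical.
#' @examples
#' segments_syntenic(c(8, -7, -6, 4), c(-4, 6, 7, 8))
#' @export
segments_syntenic <- function(s1, s2) {
  setequal(abs(as.integer(s1)), abs(as.integer(s2)))
}

#' Apply one Double-Cut-and-Join event
#'
#' Cuts the two named adjacencies of the genome and glues the four
#' exposed extremities in one of the two new ways. With `adj1 = (u1 v1)`
#' and `adj2 = (u2 v2)` in canonical form, `rewiring = 1` creates
#' `(u1 -u2)` and `(-v1 v2)`, and `rewiring = 2` creates `(u1 v2)` and
#' `(u2 v1)`. Block content is preserved; the resulting chromosomes are
#' rebuilt deterministically (linear chromosomes first, started at the
#' telomere of smallest block id; then circular ones).
#'
#' @param g a [genome()].
#' @param adj1,adj2 adjacencies present in `g`, sharing no extremity.
#' @param rewiring 1 or 2, selecting the rejoining.
#' @return the rearranged [genome()].
#' @examples
#' a <- genome("A", list(1:4))
#' apply_dcj(a, c(1, 2), c(3, 4), rewiring = 1)  # (1 -3 -2 4)
#' @export
apply_dcj <- function(g, adj1, adj2, rewiring = 1L) {
  stopifnot(inherits(g, "genome"))
  adj1 <- canonical_adjacency(adj1)
  adj2 <- canonical_adjacency(adj2)
  rewiring <- match.arg(as.character(rewiring), c("1", "2"))
  adj <- adjacencies_of(g)
  keys <- adj_keys(adj)
  for (a in list(adj1, adj2))
    if (!(paste(a[1L], a[2L]) %in% keys))
      stop("adjacency (", a[1L], " ", a[2L], ") is not present in genome ",
           g$name, call. = FALSE)
  if (adjacency_conflict(adj1, adj2) || all(adj1 == adj2))
    stop("the two adjacencies share a block extremity", call. = FALSE)
  pairs <- if (rewiring == "1")
    list(c(adj1[1L], -adj2[1L]), c(-adj1[2L], adj2[2L]))
  else
    list(c(adj1[1L], adj2[2L]), c(adj2[1L], adj1[2L]))
  if (any(vapply(pairs, function(p) abs(p[1L]) == abs(p[2L]), logical(1))))
    stop("this rewiring would circularise a single block; ",
         "use the other rewiring", call. = FALSE)
  new <- do.call(rbind, lapply(pairs, canonical_adjacency))
  keep <- adj[!(keys %in% c(paste(adj1[1L], adj1[2L]), paste(adj2[1L], adj2[2L]))), ,
              drop = FALSE]
  rebuild_genome(g$name, genome_blocks(g), as_adjacency_matrix(rbind(keep, new)))
}

# Rebuild chromosomes from a block universe and a (matching) adjacency set.
rebuild_genome <- function(name, universe, adj) {
  # partner[e] = extremity glued to e, or 0 for a telomere
  npos <- 2L * max(universe)
  partner <- integer(npos)
  e <- adj_extremities(adj)
  if (any(duplicated(c(e))))
    stop("adjacency set is conflicting; cannot rebuild a genome", call. = FALSE)
  partner[e[, 1L]] <- e[, 2L]
  partner[e[, 2L]] <- e[, 1L]
  used <- logical(npos)
  present <- logical(npos)
  present[c(2L * universe, 2L * universe - 1L)] <- TRUE

  # entering block via extremity p (= its left extremity) gives signed block
  signed_from_left <- function(p) {
    b <- (p + 1L) %/% 2L
    if (p == 2L * b - 1L) b else -b
  }
  walk <- function(start_left) {
    path <- integer(0)
    p <- start_left
    repeat {
      u <- signed_from_left(p)
      path <- c(path, u)
      used[c(2L * abs(u), 2L * abs(u) - 1L)] <<- TRUE
      r <- ext_right(u)
      q <- partner[r]
      if (q == 0L || used[2L * ((q + 1L) %/% 2L)] && used[2L * ((q + 1L) %/% 2L) - 1L])
        return(list(path = path, closed = q != 0L))
      p <- q
    }
  }
  chroms <- list()
  # linear chromosomes: start at telomeric extremities, smallest block first
  telo <- which(present & partner == 0L)
  for (t in sort(telo)) {
    b <- (t + 1L) %/% 2L
    if (used[2L * b]) next
    w <- walk(t)
    chroms[[length(chroms) + 1L]] <- chromosome(w$path, circular = FALSE)
  }
  # circular chromosomes from whatever remains
  for (b in universe) {
    if (used[2L * b]) next
    w <- walk(2L * b - 1L)
    chroms[[length(chroms) + 1L]] <- chromosome(w$path, circular = TRUE)
  }
  genome(name, chroms)
}
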