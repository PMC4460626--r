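# Signed-block and adjacency algebra.
#
# A signed block is a nonzero integer: +b reads the block forward, -b
# reversed. Each block b has two extremities, its tail and its head,
# encoded as integers 2b-1 (tail) and 2b (head). An adjacency (u v) is an
# ordered pair of consecutive signed blocks, identified with the unordered
# pair {right extremity of u, left extremity of v}; flipping the segment
# gives the identity (u v) = (-v -u).

#' Extremity identifiers of signed blocks
#'
#' The right extremity of `+b` is its head, of `-b` its tail; the left
#' extremity is the opposite. Extremities are encoded as integers
#' `2b - 1` (tail of block `b`) and `2b` (head of block `b`), so that two
#' adjacencies conflict exactly when their extremity pairs intersect.
#'
#' @param x integer vector of signed blocks (nonzero).
#' @return integer vector of extremity codes.
#' @keywords internal
#' @noRd
ext_right <- function(x) ifelse(x > 0L, 2L * x, -2L * x - 1L)

#' @noRd
ext_left <- function(x) ifelse(x > 0L, 2L * x - 1L, -2L * x)

# Ordering key for signed blocks: by block id, + before -.
block_key <- function(x) 4L * abs(x) + as.integer(x < 0L)

check_signed_blocks <- function(x) {
  if (length(x) == 0L) return(invisible(x))
  if (!is.numeric(x) || any(is.na(x)) || any(x == 0L) || any(x != trunc(x)))
    stop("signed blocks must be nonzero integers", call. = FALSE)
  invisible(as.integer(x))
}

#' Canonical form of an adjacency
#'
#' An adjacency `(u v)` and its flipped writing `(-v -u)` denote the same
#' adjacency. The canonical representative is the writing whose first
#' signed block is smallest under the ordering (block id, then `+` before
#' `-`), with the second block breaking ties. Canonicalisation is
#' idempotent.
#'
#' @param u,v signed blocks, or `u` a length-2 vector with `v` missing.
#' @return length-2 integer vector, the canonical writing.
#' @examples
#' canonical_adjacency(7, -8)   # (g -h)
#' canonical_adjacency(8, -7)   # (h -g) -> same representative
#' @export
canonical_adjacency <- function(u, v = NULL) {
  if (is.null(v)) {
    if (length(u) != 2L) stop("adjacency must have two signed blocks", call. = FALSE)
    v <- u[2L]; u <- u[1L]
  }
  u <- as.integer(u); v <- as.integer(v)
  check_signed_blocks(c(u, v))
  if (abs(u) == abs(v))
    stop("self-adjacency: the two signed blocks involve the same block id ",
         abs(u), call. = FALSE)
  a <- c(u, v)
  b <- c(-v, -u)
  ka <- block_key(a); kb <- block_key(b)
  if (ka[1L] < kb[1L] || (ka[1L] == kb[1L] && ka[2L] <= kb[2L])) a else b
}

# An adjacency set is a k x 2 integer matrix with canonical rows, unique
# and sorted. The empty set is a 0 x 2 matrix.
empty_adj <- function() matrix(integer(0), ncol = 2L)

as_adjacency_matrix <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L)
    return(empty_adj())
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 2L)
    m <- x
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, function(a) matrix(as.integer(a), ncol = 2L)))
  } else {
    m <- matrix(as.integer(x), ncol = 2L, byrow = TRUE)
  }
  m <- t(apply(m, 1L, canonical_adjacency))
  storage.mode(m) <- "integer"
  sort_adjacencies(unique(m))
}

sort_adjacencies <- function(m) {
  if (nrow(m) <= 1L) return(m)
  o <- order(block_key(m[, 1L]), block_key(m[, 2L]))
  m[o, , drop = FALSE]
}

adj_keys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste(m[, 1L], m[, 2L])
}

adj_union <- function(a, b) as_adjacency_matrix(rbind(a, b))

adj_setdiff <- function(a, b) {
  a[!(adj_keys(a) %in% adj_keys(b)), , drop = FALSE]
}

adj_intersect <- function(a, b) {
  a[adj_keys(a) %in% adj_keys(b), , drop = FALSE]
}

adj_extremities <- function(m) {
  cbind(ext_right(m[, 1L]), ext_left(m[, 2L]))
}

#' Do two adjacencies conflict?
#'
#' Two distinct adjacencies conflict when they involve a same block
#' extremity; they then cannot coexist in one genome. An adjacency never
#' conflicts with itself.
#'
#' @param a1,a2 adjacencies as length-2 signed-block vectors.
#' @return logical.
#' @examples
#' adjacency_conflict(c(7, 8), c(7, -8))  # share the head of block 7
#' adjacency_conflict(c(1, 2), c(3, 4))
#' @export
adjacency_conflict <- function(a1, a2) {
  a1 <- canonical_adjacency(a1); a2 <- canonical_adjacency(a2)
  if (all(a1 == a2)) return(FALSE)
  e1 <- c(ext_right(a1[1L]), ext_left(a1[2L]))
  e2 <- c(ext_right(a2[1L]), ext_left(a2[2L]))
  any(e1 %in% e2)
}

# Pairwise conflict matrix for an adjacency set (k x k logical).
conflict_matrix <- function(m) {
  k <- nrow(m)
  if (k == 0L) return(matrix(logical(0), 0L, 0L))
  e <- adj_extremities(m)
  shared <- outer(e[, 1L], e[, 1L], "==") | outer(e[, 1L], e[, 2L], "==") |
    outer(e[, 2L], e[, 1L], "==") | outer(e[, 2L], e[, 2L], "==")
  diag(shared) <- FALSE
  # identical rows cannot occur (sets are unique), so sharing => conflict
  shared
}
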