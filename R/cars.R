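# CARs (Contiguous Ancestral Regions) and their concatenation.

#' Construct a set of CARs
#'
#' A CAR is an ordered sequence of signed blocks hypothesised to be (part
#' of) an ancestral chromosome; a CAR and its flipped form denote the
#' same CAR. The CARs of a set partition the block universe.
#'
#' @param cars list of integer vectors of signed blocks.
#' @return an object of class `car_set`.
#' @export
car_set <- function(cars) {
  cars <- lapply(cars, function(x) {
    x <- check_signed_blocks(x)
    if (length(x) == 0L) stop("empty CAR", call. = FALSE)
    as.integer(x)
  })
  ids <- unlist(lapply(cars, abs))
  if (anyDuplicated(ids))
    stop("CARs do not partition the block universe: duplicated block ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(cars, class = "car_set")
}

#' Initial CAR set: one single-block CAR per block
#'
#' @param universe integer vector of (positive) block ids.
#' @return a [car_set()].
#' @export
initial_cars <- function(universe) {
  universe <- sort(unique(as.integer(abs(universe))))
  car_set(lapply(universe, identity))
}

flip_blocks <- function(x) -rev(x)

#' @export
print.car_set <- function(x, ...) {
  cat("CAR set with", length(x), "CARs\n")
  for (i in seq_along(x))
    cat(sprintf("  CAR %d (%d): %s\n", i, length(x[[i]]),
                paste(x[[i]], collapse = " ")))
  invisible(x)
}

car_universe <- function(cs) sort(unlist(lapply(unclass(cs), abs)))

#' Concatenate CARs along a set of non-conflicting adjacencies
#'
#' Every adjacency must join the trailing extremity of one CAR (in some
#' orientation) to the leading extremity of another; the two CARs are
#' merged, flipping as required. An adjacency whose two ends lie on the
#' same CAR would close a circular chromosome; such adjacencies are
#' skipped deterministically (adjacencies are processed in canonical sort
#' order) and reported in the `"cycle_deferred"` attribute of the result.
#'
#' @param cs a [car_set()].
#' @param adjs adjacency set (matrix, list, or vector), pairwise
#'   compatible.
#' @return the merged [car_set()]; attributes `"added"` and
#'   `"cycle_deferred"` hold the adjacency matrices actually merged and
#'   skipped.
#' @examples
#' cs <- car_set(list(c(1, 2), c(3, 4)))
#' concatenate_cars(cs, c(2, -4))  # -> (1 2 -4 -3)
#' @export
concatenate_cars <- function(cs, adjs) {
  stopifnot(inherits(cs, "car_set"))
  adjs <- as_adjacency_matrix(adjs)
  cars <- unclass(cs)
  deferred <- empty_adj()
  added <- empty_adj()
  if (nrow(adjs) >= 2L) {
    cm <- conflict_matrix(adjs)
    if (any(cm)) stop("adjacency set is conflicting", call. = FALSE)
  }
  for (r in seq_len(nrow(adjs))) {
    u <- adjs[r, 1L]; v <- adjs[r, 2L]
    iu <- iv <- NA_integer_; ou <- ov <- NULL
    for (i in seq_along(cars)) {
      b <- cars[[i]]
      if (b[length(b)] == u) { iu <- i; ou <- b }
      else if (b[1L] == -u)  { iu <- i; ou <- flip_blocks(b) }
      if (b[1L] == v)           { iv <- i; ov <- b }
      else if (b[length(b)] == -v) { iv <- i; ov <- flip_blocks(b) }
    }
    if (is.na(iu) || is.na(iv))
      stop("adjacency (", u, " ", v, ") does not join two CAR ends",
           call. = FALSE)
    if (iu == iv) {
      deferred <- rbind(deferred, adjs[r, , drop = FALSE])
      next
    }
    cars[[iu]] <- c(ou, ov)
    cars[iv] <- NULL
    added <- rbind(added, adjs[r, , drop = FALSE])
  }
  out <- car_set(cars)
  attr(out, "added") <- as_adjacency_matrix(added)
  attr(out, "cycle_deferred") <- as_adjacency_matrix(deferred)
  out
}
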