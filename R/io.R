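# Readers and writers for the block-order dialect and the step log.
#
# Block-order dialect (the de facto InferCARs/ANGES convention):
#   >GenomeName
#   1 -2 3 $          one chromosome per non-empty line; signed integer
#   4 5 @             blocks; terminator '$' = linear, '@' = circular.

#' Read signed block orders
#'
#' Parses the block-order dialect: a `>` header introduces each genome;
#' every following non-empty line is one chromosome given as
#' whitespace-separated signed integers terminated by `$` (linear) or
#' `@` (circular). All genomes must share one block universe; malformed
#' input is rejected with the offending line number, never repaired.
#'
#' @param file path to a block-order file (or `NULL` when `text` given).
#' @param text the document as a single string or character vector of
#'   lines.
#' @return named list of [genome()] objects.
#' @export
read_block_orders <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n", fixed = TRUE))
           else readLines(file)
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  flush <- function() {
    if (is.null(cur_name)) return(invisible())
    if (length(cur_chroms) == 0L)
      stop("genome ", cur_name, " has no chromosomes", call. = FALSE)
    genomes[[cur_name]] <<- genome(cur_name, cur_chroms)
    invisible()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- trimws(substring(ln, 2L))
      if (cur_name == "")
        stop("line ", i, ": empty genome name", call. = FALSE)
      if (cur_name %in% names(genomes))
        stop("line ", i, ": duplicate genome name '", cur_name, "'",
             call. = FALSE)
      cur_chroms <- list()
      next
    }
    if (is.null(cur_name))
      stop("line ", i, ": chromosome line before any '>' header", call. = FALSE)
    toks <- strsplit(ln, "[[:space:]]+")[[1L]]
    term <- toks[length(toks)]
    if (!(term %in% c("$", "@")))
      stop("line ", i, " (genome ", cur_name,
           "): chromosome must end with '$' or '@'", call. = FALSE)
    toks <- toks[-length(toks)]
    if (length(toks) == 0L)
      stop("line ", i, " (genome ", cur_name, "): empty chromosome",
           call. = FALSE)
    vals <- suppressWarnings(as.integer(toks))
    if (any(is.na(vals)) || any(vals == 0L))
      stop("line ", i, " (genome ", cur_name,
           "): blocks must be nonzero signed integers", call. = FALSE)
    cur_chroms[[length(cur_chroms) + 1L]] <-
      tryCatch(chromosome(vals, circular = term == "@"),
               error = function(e) stop("line ", i, " (genome ", cur_name,
                                        "): ", conditionMessage(e),
                                        call. = FALSE))
  }
  flush()
  if (length(genomes) == 0L) stop("no genomes in input", call. = FALSE)
  validate_genomes(genomes)
  genomes
}

#' Write signed block orders
#'
#' @param genomes named list of [genome()] objects.
#' @param file path, or `NULL` to return the text.
#' @return the text, invisibly when written to a file.
#' @export
write_block_orders <- function(genomes, file = NULL) {
  out <- character(0)
  for (g in genomes) {
    out <- c(out, paste0(">", g$name))
    for (ch in g$chromosomes)
      out <- c(out, paste(c(ch$blocks, if (ch$circular) "@" else "$"),
                          collapse = " "))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(out, file)
  invisible(txt)
}

# Orientation-normalise one CAR for output: prefer a positive leading
# block; among remaining ties take the writing that is smallest under
# the block ordering.
normalize_car <- function(x) {
  y <- flip_blocks(x)
  if ((x[1L] > 0L) != (y[1L] > 0L)) return(if (x[1L] > 0L) x else y)
  kx <- block_key(x); ky <- block_key(y)
  d <- which(kx != ky)
  if (length(d) == 0L || kx[d[1L]] < ky[d[1L]]) x else y
}

#' Write a CAR set in the block-order dialect
#'
#' CARs are written as the chromosomes of a genome named `ANCESTOR`,
#' sorted by decreasing block count then by smallest block id, each
#' orientation-normalised so that the leading block is positive whenever
#' one of the two writings allows it.
#'
#' @param cs a [car_set()].
#' @param file path, or `NULL` to return the text.
#' @return the text, invisibly when written to a file.
#' @export
write_cars <- function(cs, file = NULL) {
  stopifnot(inherits(cs, "car_set"))
  cars <- lapply(unclass(cs), normalize_car)
  o <- order(-lengths(cars), vapply(cars, function(x) min(abs(x)), integer(1)))
  g <- genome("ANCESTOR", cars[o])
  write_block_orders(list(g), file)
}

#' Write the per-step log as TSV
#'
#' One row per step of a [run_procars()] result: step index, kind,
#' number of CARs, CAR size range, number of adjacencies added.
#'
#' @param steps the `steps` element of a [run_procars()] result.
#' @param file path, or `NULL` to return the data frame only.
#' @return data frame of the log, invisibly when written.
#' @export
write_step_log <- function(steps, file = NULL) {
  df <- do.call(rbind, lapply(steps, function(s)
    data.frame(step = s$step_index, kind = s$step_kind,
               n_cars = s$n_cars_after,
               size_min = s$car_size_range[1L],
               size_max = s$car_size_range[2L],
               n_added = s$n_added)))
  if (!is.null(file)) {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
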