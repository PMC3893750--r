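#' Tag libraries
#'
#' A tag library holds the unitag counts of one HT-SuperSAGE sequencing
#' library together with its bulk phenotype and treatment. `N` is the total
#' number of sequenced tags and is the normalisation base for
#' tags-per-million; it is deliberately kept separate from the sum of the
#' retained counts so that filters (singleton exclusion) do not change the
#' normalisation.
#'
#' @param id Library label, e.g. `"SD24T"`.
#' @param bulk Either `"tolerant"` or `"sensitive"`.
#' @param treatment Either `"stress"` or `"control"`.
#' @param counts Named non-negative integer vector, names are unitag
#'   sequences.
#' @param N Total sequenced tag count; defaults to `sum(counts)`.
#' @return An object of class `tag_library`.
#' @export
tag_library <- function(id, bulk = c("tolerant", "sensitive"),
                        treatment = c("stress", "control"),
                        counts = integer(), N = sum(counts)) {
  bulk <- match.arg(bulk)
  treatment <- match.arg(treatment)
  if (length(counts) && is.null(names(counts)))
    stop("counts must be named by unitag sequence")
  counts <- stats::setNames(as.integer(round(counts)), names(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (N < sum(counts)) stop("N cannot be smaller than the retained counts")
  structure(list(id = id, bulk = bulk, treatment = treatment,
                 counts = counts, N = as.numeric(N)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("<tag_library> %s (%s bulk, %s): %d unitags, N = %s tags\n",
              x$id, x$bulk, x$treatment, length(x$counts),
              format(x$N, big.mark = ",")))
  invisible(x)
}

TAG_LENGTH <- 26L
TAG_ANCHOR <- "CATG"

#' Extract 26-bp NlaIII-anchored tags from transcript sequences
#'
#' SuperSAGE tags are the 26 bp starting at an NlaIII recognition site
#' (CATG) of the transcript. The canonical tag is taken at the 3'-most CATG
#' that still has at least 22 nt downstream (so a full 26-mer fits). With
#' `partial = TRUE` every qualifying site yields a tag, modelling partial
#' NlaIII digestion which leaves internal-site tags in real libraries.
#'
#' Windows containing non-ACGT characters are skipped with a warning; in
#' canonical mode the next 3'-most clean site is used instead.
#'
#' @param sequences Character vector of uppercase DNA sequences (ambiguity
#'   characters allowed outside the returned window), or a
#'   [Biostrings::DNAStringSet].
#' @param partial Report tags for all qualifying CATG sites instead of only
#'   the 3'-most one.
#' @return In canonical mode, a character vector parallel to `sequences`
#'   (`NA` where no tag is extractable). With `partial = TRUE`, a list of
#'   character vectors (possibly empty), ordered 5' to 3'.
#' @export
extract_tag <- function(sequences, partial = FALSE) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  stopifnot(is.character(sequences))
  site_tags <- function(s) {
    hits <- gregexpr(TAG_ANCHOR, s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(character())
    starts <- hits[hits + TAG_LENGTH - 1L <= nchar(s)]
    if (!length(starts)) return(character())
    tags <- substring(s, starts, starts + TAG_LENGTH - 1L)
    clean <- !grepl("[^ACGT]", tags)
    if (any(!clean))
      warning("skipping tag window(s) with non-ACGT characters",
              call. = FALSE)
    tags[clean]
  }
  res <- lapply(sequences, site_tags)
  if (partial) return(res)
  vapply(res, function(t) if (length(t)) t[length(t)] else NA_character_,
         character(1))
}

is_valid_unitag <- function(tags) {
  !is.na(tags) & nchar(tags) == TAG_LENGTH &
    startsWith(tags, TAG_ANCHOR) & !grepl("[^ACGT]", tags)
}

#' Aggregate a tag stream into a unitag count library
#'
#' @param tags Character vector of observed 26-bp tags (one element per
#'   sequenced tag). Malformed entries (wrong length, missing CATG prefix,
#'   non-ACGT) are dropped with a warning naming their positions.
#' @inheritParams tag_library
#' @return A [tag_library] whose `N` equals the number of valid input tags.
#' @export
count_tags <- function(tags, id = "library", bulk = "tolerant",
                       treatment = "stress") {
  ok <- is_valid_unitag(tags)
  if (any(!ok)) {
    bad <- which(!ok)
    warning(sprintf("dropping %d malformed tag(s) at line(s) %s",
                    length(bad),
                    paste(utils::head(bad, 10L), collapse = ", ")),
            call. = FALSE)
    tags <- tags[ok]
  }
  counts <- if (length(tags)) {
    tab <- table(tags)
    stats::setNames(as.integer(tab), names(tab))
  } else integer()
  tag_library(id, bulk, treatment, counts, N = length(tags))
}

#' Remove per-library singletons
#'
#' Unitags sequenced exactly once in a library are considered unreliable and
#' removed from that library's count map. The removal is per-library: a
#' singleton here may persist in another library. `N` (the sequenced total)
#' is not changed, so tags-per-million keeps its original base.
#'
#' @param library A [tag_library].
#' @return The filtered [tag_library].
#' @export
exclude_singletons <- function(library) {
  stopifnot(inherits(library, "tag_library"))
  library$counts <- library$counts[library$counts != 1L]
  library
}

#' Normalise a library to tags per million
#'
#' tpm(u) = count(u) * 1e6 / N, with N the total sequenced tags of the
#' library (before any singleton exclusion). Full floating precision is
#' kept; rounding is a display concern of the reporting layer.
#'
#' @param library A [tag_library] with `N > 0`.
#' @return Named numeric vector of tpm values.
#' @export
normalize_tpm <- function(library) {
  stopifnot(inherits(library, "tag_library"))
  if (library$N <= 0) stop("library total N must be positive")
  library$counts * 1e6 / library$N
}

#' Combine per-library tpm vectors into one table
#'
#' @param libraries Named list of [tag_library] objects.
#' @return Data frame with a `unitag` column and one tpm column per library
#'   (0 where a unitag is absent from a library).
#' @export
tpm_table <- function(libraries) {
  stopifnot(length(libraries) > 0)
  if (is.null(names(libraries)))
    names(libraries) <- vapply(libraries, `[[`, character(1), "id")
  tpms <- lapply(libraries, normalize_tpm)
  unitags <- sort(unique(unlist(lapply(tpms, names), use.names = FALSE)))
  out <- data.frame(unitag = unitags, stringsAsFactors = FALSE)
  for (nm in names(libraries)) {
    v <- tpms[[nm]][unitags]
    v[is.na(v)] <- 0
    out[[nm]] <- unname(v)
  }
  out
}

#' Read / write two-column tag count files
#'
#' The on-disk format is headerless TSV: tag sequence, count.
#'
#' @param path File path.
#' @inheritParams tag_library
#' @return `read_library` returns a [tag_library]; `write_library` returns
#'   `path` invisibly.
#' @export
read_library <- function(path, id = basename(path), bulk = "tolerant",
                         treatment = "stress", N = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("tag", "count"),
                          colClasses = c("character", "integer"))
  counts <- stats::setNames(df$count, df$tag)
  tag_library(id, bulk, treatment, counts,
              N = if (is.null(N)) sum(counts) else N)
}

#' @rdname read_library
#' @param library A [tag_library] to serialise.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "tag_library"))
  ord <- order(names(library$counts))
  utils::write.table(
    data.frame(tag = names(library$counts)[ord],
               count = unname(library$counts)[ord]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
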