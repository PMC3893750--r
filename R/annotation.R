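#' EST reference collections
#'
#' A reference is a data frame with one row per EST: `id`, `database`
#' (source databank label), `species`, `annotation` (free-text functional
#' description), `go_terms` (semicolon-separated), `sequence` (DNA).
#'
#' @param id,database,species,annotation,go_terms,sequence Parallel vectors.
#' @return A data frame of class `est_reference`.
#' @export
est_reference <- function(id, database, species, annotation, go_terms,
                          sequence) {
  if (anyDuplicated(paste(database, id)))
    stop("EST ids must be unique within a database")
  structure(
    data.frame(id = id, database = database, species = species,
               annotation = annotation, go_terms = go_terms,
               sequence = sequence, stringsAsFactors = FALSE),
    class = c("est_reference", "data.frame"))
}

#' Default EST database priority
#'
#' Ranked databank labels used by [best_hit()]: the sugarcane sources
#' (dbEST, SoGI) first, then Gene Index databanks of progressively less
#' related grasses.
#'
#' @return Character vector, highest priority first.
#' @export
default_db_priority <- function() {
  c("dbEST", "SoGI", "SbGI", "ZmGI", "OsGI", "PaviGI", "TaGI", "HvGI",
    "FaGI")
}

#' Read / write an EST reference (FASTA + annotation TSV)
#'
#' @param fasta Path to the sequence FASTA.
#' @param annotations Path to the annotation table (TSV with header:
#'   id, database, species, annotation, go_terms).
#' @return An `est_reference`.
#' @export
read_reference <- function(fasta, annotations) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ann <- utils::read.table(annotations, sep = "\t", header = TRUE,
                           quote = "", colClasses = "character")
  seq_chr <- stats::setNames(as.character(seqs), names(seqs))
  if (!all(ann$id %in% names(seq_chr)))
    stop("annotation table references ids absent from the FASTA")
  est_reference(ann$id, ann$database, ann$species, ann$annotation,
                ann$go_terms, unname(seq_chr[ann$id]))
}

#' @rdname read_reference
#' @param reference An `est_reference` to serialise.
#' @export
write_reference <- function(reference, fasta, annotations) {
  seqs <- Biostrings::DNAStringSet(reference$sequence)
  names(seqs) <- reference$id
  Biostrings::writeXStringSet(seqs, fasta)
  utils::write.table(reference[, c("id", "database", "species",
                                   "annotation", "go_terms")],
                     annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fasta)
}

empty_hits <- function() {
  data.frame(unitag = character(), est = character(),
             database = character(), start = integer(), m = integer(),
             mismatches = integer(), score = integer(),
             stringsAsFactors = FALSE)
}

#' Anchor a unitag on an EST reference
#'
#' Models the BLASTn acceptance rules for 26-bp tag-to-EST alignments:
#' sense strand only, 5' CATG preserved, and either
#' \describe{
#'   \item{`exact-prefix`}{a prefix of the unitag of length `m` in 21..26
#'     matching the EST exactly; the longest such `m` is reported per
#'     (EST, offset), with score `2 * m` (42..52).}
#'   \item{`one-mismatch`}{the full 26-mer aligned with at most one
#'     substitution, never inside the leading CATG (0-based positions
#'     4..25 only).}
#' }
#' Reverse-complement matches are never reported.
#'
#' @param unitag A 26-nt unitag sequence starting with CATG.
#' @param reference An `est_reference`.
#' @param mode `"exact-prefix"` (default) or `"one-mismatch"`.
#' @return Data frame of hits: `unitag`, `est`, `database`, `start`
#'   (0-based offset on the EST), `m`, `mismatches`, `score`. Zero rows is
#'   a valid outcome.
#' @export
anchor <- function(unitag, reference,
                   mode = c("exact-prefix", "one-mismatch")) {
  mode <- match.arg(mode)
  stopifnot(is.character(unitag), length(unitag) == 1L)
  if (!is_valid_unitag(unitag))
    stop("unitag must be 26 nt, ACGT only, starting with CATG")
  if (!nrow(reference)) stop("reference is empty")
  out <- vector("list", nrow(reference))
  min_m <- 21L
  prefix <- substr(unitag, 1L, min_m)
  tagv <- strsplit(unitag, "")[[1]]
  for (i in seq_len(nrow(reference))) {
    s <- reference$sequence[i]
    if (mode == "exact-prefix") {
      # every prefix occurrence starts at a CATG site, and CATG cannot
      # overlap itself, so scanning CATG sites finds all (even overlapping)
      # prefix matches
      pos <- gregexpr(TAG_ANCHOR, s, fixed = TRUE)[[1]]
      pos <- pos[pos != -1L & pos + min_m - 1L <= nchar(s)]
      if (!length(pos)) next
      pos <- pos[substring(s, pos, pos + min_m - 1L) == prefix]
      if (!length(pos)) next
      m <- vapply(pos, function(p) {
        len <- min_m
        while (len < TAG_LENGTH && p + len <= nchar(s) &&
               substr(s, p + len, p + len) == tagv[len + 1L])
          len <- len + 1L
        len
      }, integer(1))
      out[[i]] <- data.frame(
        unitag = unitag, est = reference$id[i],
        database = reference$database[i], start = as.integer(pos - 1L),
        m = m, mismatches = 0L, score = 2L * m,
        stringsAsFactors = FALSE)
    } else {
      pos <- gregexpr(TAG_ANCHOR, s, fixed = TRUE)[[1]]
      pos <- pos[pos != -1L & pos + TAG_LENGTH - 1L <= nchar(s)]
      if (!length(pos)) next
      keep <- integer(0); mm <- integer(0)
      for (p in pos) {
        win <- strsplit(substr(s, p, p + TAG_LENGTH - 1L), "")[[1]]
        d <- which(win != tagv)
        if (length(d) <= 1L && all(d >= 5L)) {   # 1-based: CATG is 1..4
          keep <- c(keep, p); mm <- c(mm, length(d))
        }
      }
      if (!length(keep)) next
      out[[i]] <- data.frame(
        unitag = unitag, est = reference$id[i],
        database = reference$database[i], start = as.integer(keep - 1L),
        m = TAG_LENGTH, mismatches = mm,
        score = 2L * (TAG_LENGTH - mm),
        stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_hits())
  do.call(rbind, out)
}

#' Anchor many unitags
#'
#' @param unitags Character vector of unitags.
#' @inheritParams anchor
#' @return Row-bound hit table (see [anchor()]).
#' @export
anchor_all <- function(unitags, reference,
                       mode = c("exact-prefix", "one-mismatch")) {
  mode <- match.arg(mode)
  do.call(rbind, c(lapply(unitags, anchor, reference = reference,
                          mode = mode),
                   list(empty_hits())))
}

DENY_ANNOTATION <- "unknown|hypothetical|unnamed"

adequate_annotation <- function(annotation,
                                deny_pattern = DENY_ANNOTATION) {
  !is.na(annotation) & nzchar(trimws(annotation)) &
    !grepl(deny_pattern, annotation, ignore.case = TRUE)
}

#' Select the best hit of a unitag
#'
#' Deterministic ranking of accepted anchor hits: (1) adequately annotated
#' ESTs first (annotation non-empty and not matching the deny pattern for
#' uninformative descriptions), (2) database priority (sugarcane sources
#' first), (3) score descending, (4) EST id as final lexicographic
#' tie-break. The winner does not depend on the input row order.
#'
#' @param hits Hit table for one unitag (as produced by [anchor()]).
#' @param reference The `est_reference` supplying annotations.
#' @param db_priority Ranked database labels, see [default_db_priority()].
#' @param deny_pattern Case-insensitive regex marking inadequate
#'   annotations.
#' @return A one-row hit data frame, or `NULL` for an empty hit list.
#' @export
best_hit <- function(hits, reference, db_priority = default_db_priority(),
                     deny_pattern = DENY_ANNOTATION) {
  if (is.null(hits) || !nrow(hits)) return(NULL)
  if (length(unique(hits$unitag)) != 1L)
    stop("best_hit expects hits of a single unitag")
  key <- paste(reference$database, reference$id)
  ann <- reference$annotation[match(paste(hits$database, hits$est), key)]
  adequate <- adequate_annotation(ann, deny_pattern)
  rank_db <- match(hits$database, db_priority)
  rank_db[is.na(rank_db)] <- length(db_priority) + 1L
  ord <- order(!adequate, rank_db, -hits$score, hits$est, hits$start)
  hits[ord[1L], , drop = FALSE]
}

#' Default aquaporin mining keywords
#'
#' The annotation keywords used to flag major-intrinsic-protein (aquaporin)
#' records, combining full names and the four subfamily codes.
#'
#' @return Character vector of keywords.
#' @export
default_family_keywords <- function() {
  c("aquaporin", "major intrinsic protein",
    "plasma membrane intrinsic protein", "tonoplast intrinsic protein",
    "nodulin-26-like intrinsic protein", "small basic intrinsic protein",
    "water channel",
    "PIP", "TIP", "NIP", "SIP")
}

#' Flag gene-family records by annotation keywords and GO terms
#'
#' Long keywords (two or more words, or at least 8 characters) are matched
#' case-insensitively as substrings of the annotation. Short family codes
#' (PIP, TIP, NIP, SIP) are matched case-sensitively and only at token
#' boundaries -- no adjacent letters, digits allowed -- so "PIP2-4" matches
#' while "pipecolate" and "PIPELINE" do not. A GO route matches when any GO
#' term contains `go_phrase`.
#'
#' @param reference An `est_reference` (or any data frame with
#'   `annotation` and `go_terms` columns).
#' @param keywords Annotation keywords; see [default_family_keywords()].
#' @param go_phrase Phrase searched case-insensitively in the GO terms.
#' @return Data frame with `id`, `matched` (logical) and `source`
#'   (`"annotation"`, `"go"`, `"both"` or `NA` when unmatched).
#' @export
mine_family <- function(reference, keywords = default_family_keywords(),
                        go_phrase = "water transport") {
  if (!length(keywords)) stop("keyword list must not be empty")
  long <- grepl(" ", keywords) | nchar(keywords) >= 8L
  ann_hit <- rep(FALSE, nrow(reference))
  for (kw in keywords[long])
    ann_hit <- ann_hit | grepl(kw, reference$annotation, fixed = FALSE,
                               ignore.case = TRUE)
  for (kw in keywords[!long]) {
    pat <- sprintf("(?<![A-Za-z])%s(?![A-Za-z])", kw)
    ann_hit <- ann_hit | grepl(pat, reference$annotation, perl = TRUE)
  }
  go_hit <- grepl(go_phrase, reference$go_terms, ignore.case = TRUE)
  source <- rep(NA_character_, nrow(reference))
  source[ann_hit & !go_hit] <- "annotation"
  source[!ann_hit & go_hit] <- "go"
  source[ann_hit & go_hit] <- "both"
  data.frame(id = reference$id, matched = ann_hit | go_hit,
             source = source, stringsAsFactors = FALSE)
}

SUBFAMILIES <- c("PIP", "TIP", "NIP", "SIP")

.parse_one_label <- function(text) {
  m <- regmatches(text, regexec(
    "(PIP|TIP|NIP|SIP)[ -]?([0-9]+)(?:[-;., ]([0-9]+))?", text))[[1]]
  if (!length(m)) return(NULL)
  label <- if (is.na(m[4]) || !nzchar(m[4])) paste0(m[2], m[3])
           else paste0(m[2], m[3], "-", m[4])
  list(subfamily = m[2], label = label)
}

#' Parse an aquaporin isoform identity out of an annotation
#'
#' Extracts the subfamily code (PIP/TIP/NIP/SIP) plus group and member
#' numbering, tolerating the separators used across databanks ("PIP2-4",
#' "TIP1;1", "PIP 2.4"), and normalises to `"<SUBFAMILY><group>-<member>"`.
#' Dual labels such as "PIP1-3/PIP1-4" (isoforms indistinguishable at the
#' tag level) are preserved verbatim after normalising each side.
#'
#' @param annotation Free-text annotation.
#' @param species Abbreviated species prefix carried through (e.g. "So").
#' @return A list with `subfamily`, `label`, `species`, or `NULL` when no
#'   isoform pattern is present.
#' @export
parse_isoform <- function(annotation, species = NA_character_) {
  if (is.na(annotation) || !nzchar(annotation)) return(NULL)
  dual <- regmatches(annotation, regexec(
    paste0("((?:PIP|TIP|NIP|SIP)[ -]?[0-9]+(?:[-;., ][0-9]+)?)",
           "\\s*/\\s*",
           "((?:PIP|TIP|NIP|SIP)[ -]?[0-9]+(?:[-;., ][0-9]+)?)"),
    annotation))[[1]]
  if (length(dual)) {
    a <- .parse_one_label(dual[2])
    b <- .parse_one_label(dual[3])
    return(list(subfamily = a$subfamily,
                label = paste0(a$label, "/", b$label),
                species = species))
  }
  one <- .parse_one_label(annotation)
  if (is.null(one)) return(NULL)
  list(subfamily = one$subfamily, label = one$label, species = species)
}

isoform_subclass <- function(labels) {
  # subfamily + group of the first component, e.g. "PIP1-3/PIP1-4" -> "PIP1"
  sub("^((PIP|TIP|NIP|SIP)[0-9]+).*", "\\1", labels)
}

#' Round a count ratio to a percentage
#'
#' @param k Numerator count(s).
#' @param n Denominator count.
#' @param digits Decimal places of the printed percentage (default 0).
#' @return `round(100 * k / n, digits)`.
#' @export
tally_percent <- function(k, n, digits = 0) {
  if (n <= 0) stop("denominator must be positive")
  round(100 * k / n, digits)
}

#' Tally unitag specificity across anchored isoforms
#'
#' A unitag whose accepted hits all carry the same isoform label is
#' isoform-specific; when they only share the subfamily+group subclass
#' (e.g. all PIP2) it is subclass-specific; otherwise it is nonspecific.
#'
#' @param isoforms_by_unitag Named list: unitag -> character vector of the
#'   isoform labels of its accepted hits.
#' @param digits Decimal places for the reported percentages.
#' @return List with `counts` and `percent`, each a named numeric vector
#'   over `isoform`, `subclass`, `nonspecific`, plus `n` (unitag total).
#' @export
specificity_tally <- function(isoforms_by_unitag, digits = 0) {
  classify <- function(labels) {
    labels <- labels[!is.na(labels)]
    if (!length(labels)) return(NA_character_)
    if (length(unique(labels)) == 1L) return("isoform")
    if (length(unique(isoform_subclass(labels))) == 1L) return("subclass")
    "nonspecific"
  }
  cls <- vapply(isoforms_by_unitag, classify, character(1))
  cls <- cls[!is.na(cls)]
  counts <- c(isoform = sum(cls == "isoform"),
              subclass = sum(cls == "subclass"),
              nonspecific = sum(cls == "nonspecific"))
  list(counts = counts,
       percent = tally_percent(counts, length(cls), digits),
       n = length(cls))
}
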