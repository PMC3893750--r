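subfamily_order <- function(labels) {
  sf <- sub("^((PIP|TIP|NIP|SIP)).*", "\\1", labels)
  m <- match(sf, SUBFAMILIES)
  m[is.na(m)] <- length(SUBFAMILIES) + 1L   # "unassigned" sorts last
  m
}

#' Isoform-level UR/DR/ns summary per contrast
#'
#' Counts, for every isoform and contrast, how many of its unitags were
#' called up-regulated, down-regulated, or not significant. Unitags without
#' an isoform assignment are routed to an `"unassigned"` bucket, never
#' dropped, so the table conserves the number of observed mapped unitags.
#' Rows are ordered by subfamily (PIP, TIP, NIP, SIP) then label.
#'
#' @param results Named list of contrast result data frames
#'   ([run_contrast()]).
#' @param isoform_map Data frame with columns `unitag`, `isoform`.
#' @return Data frame: `isoform`, `contrast`, `UR`, `DR`, `ns`.
#' @export
isoform_table <- function(results, isoform_map) {
  if (is.null(names(results)))
    names(results) <- vapply(results, attr, character(1), "contrast")
  rows <- list()
  for (cn in names(results)) {
    res <- results[[cn]]
    if (!nrow(res)) next
    iso <- isoform_map$isoform[match(res$unitag, isoform_map$unitag)]
    iso[is.na(iso)] <- "unassigned"
    tab <- table(isoform = iso,
                 call = factor(res$call, levels = c("UR", "DR", "ns")))
    df <- as.data.frame.matrix(tab)
    rows[[cn]] <- data.frame(isoform = rownames(df), contrast = cn,
                             UR = df$UR, DR = df$DR, ns = df$ns,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(isoform = character(), contrast = character(),
                      UR = integer(), DR = integer(), ns = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(subfamily_order(out$isoform), out$isoform,
                   out$contrast), ]
  rownames(out) <- NULL
  out
}

#' Top expressed family unitags across libraries
#'
#' Ranks family-matched unitags by their maximum tpm over the libraries
#' (ties broken by total tpm, then unitag id) and returns the top `n` with
#' per-library tpm rounded to integers (full precision lives upstream).
#'
#' @param tpms A [tpm_table()] data frame (`unitag` + one column per
#'   library).
#' @param n Number of rows to keep; if fewer unitags exist, all are
#'   returned.
#' @param unitags Optional character vector restricting the universe (e.g.
#'   the family-annotated unitags).
#' @param annotations Optional data frame `unitag`, `annotation` merged
#'   into the output.
#' @return Data frame of the top `n` rows.
#' @export
top_expressed <- function(tpms, n = 30, unitags = NULL,
                          annotations = NULL) {
  if (n <= 0) stop("n must be positive")
  lib_cols <- setdiff(names(tpms), "unitag")
  df <- if (is.null(unitags)) tpms else tpms[tpms$unitag %in% unitags, ]
  if (!nrow(df)) return(df)
  mx <- do.call(pmax, df[lib_cols])
  tot <- Reduce(`+`, df[lib_cols])
  df <- df[order(-mx, -tot, df$unitag), ]
  df <- utils::head(df, n)
  for (cl in lib_cols) df[[cl]] <- round(df[[cl]])
  if (!is.null(annotations))
    df$annotation <-
      annotations$annotation[match(df$unitag, annotations$unitag)]
  rownames(df) <- NULL
  df
}

#' Cross-contrast divergence table
#'
#' Joins two contrasts (tolerant and sensitive bulks against their
#' controls) and keeps every unitag significant in at least one of them,
#' with both fold changes and calls side by side. Cross-tabulated summary
#' counts (e.g. how many tolerant-UR unitags were sensitive-DR) are
#' attached as attribute `"summary"`.
#'
#' @param res_tolerant,res_sensitive Contrast results ([run_contrast()]).
#' @param annotations Optional `unitag`/`annotation` map.
#' @return Data frame: `unitag`, `annotation`, `FC_tolerant`,
#'   `call_tolerant`, `FC_sensitive`, `call_sensitive`.
#' @export
divergence_table <- function(res_tolerant, res_sensitive,
                             annotations = NULL) {
  common <- intersect(res_tolerant$unitag, res_sensitive$unitag)
  if (length(common) < length(union(res_tolerant$unitag,
                                    res_sensitive$unitag)))
    warning("contrast universes differ; using their intersection",
            call. = FALSE)
  t <- res_tolerant[match(common, res_tolerant$unitag), ]
  s <- res_sensitive[match(common, res_sensitive$unitag), ]
  keep <- t$call != "ns" | s$call != "ns"
  out <- data.frame(unitag = common[keep],
                    annotation = NA_character_,
                    FC_tolerant = t$FC[keep],
                    call_tolerant = t$call[keep],
                    FC_sensitive = s$FC[keep],
                    call_sensitive = s$call[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(annotations))
    out$annotation <-
      annotations$annotation[match(out$unitag, annotations$unitag)]
  out <- out[order(out$unitag), ]
  rownames(out) <- NULL
  lv <- c("UR", "DR", "ns")
  attr(out, "summary") <- table(tolerant = factor(t$call[keep], lv),
                                sensitive = factor(s$call[keep], lv))
  out
}

#' Candidate expression markers from isoform regulation patterns
#'
#' Flags isoforms whose unitag calls form marker-grade patterns:
#' \describe{
#'   \item{exclusive-UR}{at least one UR and no DR unitag within one
#'     contrast (exclusive-DR symmetric);}
#'   \item{divergent}{UR in the tolerant contrast and DR in the sensitive
#'     one (or vice versa), via the same or different unitags.}
#' }
#' Output is independent of input row order.
#'
#' @param summaries [isoform_table()] output; the divergent pattern uses
#'   the contrasts named in `tolerant` / `sensitive`.
#' @param tolerant,sensitive Contrast names of the tolerant and sensitive
#'   bulk comparisons (for the divergent pattern; skipped when absent).
#' @param divergence Optional [divergence_table()] used to attach the
#'   supporting unitags and fold changes of divergent isoforms, together
#'   with an `isoform_map` (`unitag`, `isoform`).
#' @param isoform_map Optional `unitag`/`isoform` map for support lookup.
#' @return Data frame: `isoform`, `pattern`, `contrast`, `support`.
#' @export
candidate_markers <- function(summaries, tolerant = "tolerant",
                              sensitive = "sensitive",
                              divergence = NULL, isoform_map = NULL) {
  out <- list()
  excl <- summaries[summaries$isoform != "unassigned" &
                      ((summaries$UR > 0 & summaries$DR == 0) |
                         (summaries$DR > 0 & summaries$UR == 0)), ]
  if (nrow(excl))
    out$exclusive <- data.frame(
      isoform = excl$isoform,
      pattern = ifelse(excl$UR > 0, "exclusive-UR", "exclusive-DR"),
      contrast = excl$contrast, support = NA_character_,
      stringsAsFactors = FALSE)
  st <- summaries[summaries$contrast == tolerant, ]
  ss <- summaries[summaries$contrast == sensitive, ]
  if (nrow(st) && nrow(ss)) {
    iso <- intersect(st$isoform, ss$isoform)
    iso <- setdiff(iso, "unassigned")
    t <- st[match(iso, st$isoform), ]
    s <- ss[match(iso, ss$isoform), ]
    div <- (t$UR > 0 & s$DR > 0) | (t$DR > 0 & s$UR > 0)
    if (any(div)) {
      support <- rep(NA_character_, sum(div))
      if (!is.null(divergence) && !is.null(isoform_map)) {
        dv <- divergence
        dv$isoform <- isoform_map$isoform[match(dv$unitag,
                                                isoform_map$unitag)]
        support <- vapply(iso[div], function(i) {
          rows <- dv[!is.na(dv$isoform) & dv$isoform == i &
                       dv$call_tolerant != dv$call_sensitive &
                       dv$call_tolerant != "ns" & dv$call_sensitive != "ns",
                     , drop = FALSE]
          if (!nrow(rows)) return(NA_character_)
          paste(sprintf("%s (%.2f/%.2f)", rows$unitag, rows$FC_tolerant,
                        rows$FC_sensitive), collapse = "; ")
        }, character(1))
      }
      out$divergent <- data.frame(
        isoform = iso[div], pattern = "divergent",
        contrast = paste(tolerant, "vs", sensitive),
        support = unname(support), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(isoform = character(), pattern = character(),
                      contrast = character(), support = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(subfamily_order(res$isoform), res$isoform,
                   res$pattern, res$contrast), ]
  rownames(res) <- NULL
  res
}

#' Isoform-by-contrast fold-change matrix
#'
#' One cell per (isoform, contrast): the signed fold change of the
#' isoform's most extreme significant unitag (largest `|FC|` with call !=
#' ns), or 0 when the isoform has no significant unitag in that contrast.
#' Intended as the machine-readable input of a fold-change heat map.
#'
#' @inheritParams isoform_table
#' @return Numeric matrix, isoforms x contrasts, subfamily-ordered rows.
#' @export
fc_matrix <- function(results, isoform_map) {
  if (is.null(names(results)))
    names(results) <- vapply(results, attr, character(1), "contrast")
  isoforms <- sort(unique(isoform_map$isoform))
  isoforms <- isoforms[order(subfamily_order(isoforms), isoforms)]
  mat <- matrix(0, length(isoforms), length(results),
                dimnames = list(isoforms, names(results)))
  for (cn in names(results)) {
    res <- results[[cn]]
    res$isoform <- isoform_map$isoform[match(res$unitag,
                                             isoform_map$unitag)]
    sig <- res[!is.na(res$isoform) & res$call != "ns", ]
    if (!nrow(sig)) next
    for (i in unique(sig$isoform)) {
      fcs <- sig$FC[sig$isoform == i]
      mat[i, cn] <- fcs[which.max(abs(fcs))]
    }
  }
  mat
}

#' Write a report table as TSV
#'
#' Deterministic text serialisation used for all report artifacts; numeric
#' columns are written at full precision unless `digits` is given.
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @param digits Optional rounding applied to numeric columns for display
#'   tables.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, digits = NULL) {
  if (is.matrix(x))
    x <- data.frame(isoform = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.null(digits))
    for (nm in names(x))
      if (is.numeric(x[[nm]])) x[[nm]] <- round(x[[nm]], digits)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
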