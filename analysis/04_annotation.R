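#!/usr/bin/env Rscript
# Stage 4: aquaporin mining of the EST reference, anchoring of every
# observed unitag to the mined family records, best-hit selection, isoform
# parsing and the unitag specificity tally.

source(file.path("analysis", "00_config.R"))

ref <- read_reference(file.path(DATA_DIR, "reference.fasta"),
                      file.path(DATA_DIR, "reference_annotations.tsv"))
mined <- mine_family(ref)
family_ref <- ref[mined$matched, ]
cat(sprintf("family mining: %d of %d ESTs matched (%d annotation, %d GO-only)\n",
            nrow(family_ref), nrow(ref),
            sum(mined$source %in% c("annotation", "both")),
            sum(mined$source == "go", na.rm = TRUE)))

observed <- unique(unlist(lapply(LIB_IDS, function(id)
  names(read_library(file.path(DATA_DIR, paste0(id, "_filtered.tsv")),
                     id = id)$counts))))
hits <- anchor_all(sort(observed), family_ref, mode = "exact-prefix")
cat(sprintf("anchoring: %d observed unitags, %d accepted hits, %d unitags anchored\n",
            length(observed), nrow(hits), length(unique(hits$unitag))))

best <- do.call(rbind, lapply(split(hits, hits$unitag), best_hit,
                              reference = ref))
ann <- ref$annotation[match(paste(best$database, best$est),
                            paste(ref$database, ref$id))]
iso <- vapply(ann, function(a) {
  p <- parse_isoform(a)
  if (is.null(p)) NA_character_ else p$label
}, character(1), USE.NAMES = FALSE)
map <- data.frame(unitag = best$unitag, isoform = iso, annotation = ann,
                  stringsAsFactors = FALSE)
write_report(cbind(best, annotation = ann, isoform = iso),
             file.path(TABLE_DIR, "best_hits.tsv"))
write_report(map, file.path(TABLE_DIR, "isoform_map.tsv"))

# specificity: do all of a unitag's accepted hits agree on the isoform?
per_unitag <- lapply(split(hits, hits$unitag), function(h) {
  a <- ref$annotation[match(paste(h$database, h$est),
                            paste(ref$database, ref$id))]
  vapply(a, function(x) {
    p <- parse_isoform(x)
    if (is.null(p)) NA_character_ else p$label
  }, character(1), USE.NAMES = FALSE)
})
tally <- specificity_tally(per_unitag)
cat(sprintf("specificity over %d anchored unitags: %d isoform-specific (%d%%), %d subclass (%d%%), %d nonspecific (%d%%)\n",
            tally$n, tally$counts["isoform"], tally$percent["isoform"],
            tally$counts["subclass"], tally$percent["subclass"],
            tally$counts["nonspecific"], tally$percent["nonspecific"]))
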