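#!/usr/bin/env Rscript
# Stage 5: isoform-level summary artifacts -- UR/DR/ns table per contrast,
# top-expressed table, cross-contrast divergence, candidate markers and
# the fold-change matrix for heat-map rendering.

source(file.path("analysis", "00_config.R"))

results <- list()
for (cn in c("tolerant", "sensitive")) {
  res <- read.table(file.path(TABLE_DIR, paste0("contrast_", cn, ".tsv")),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  attr(res, "contrast") <- cn
  results[[cn]] <- res
}
map <- read.table(file.path(TABLE_DIR, "isoform_map.tsv"), sep = "\t",
                  header = TRUE, stringsAsFactors = FALSE)
tpms <- read.table(file.path(TABLE_DIR, "tpm_table.tsv"), sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)

tab <- isoform_table(results, map)
write_report(tab, file.path(TABLE_DIR, "isoform_table.tsv"))
cat(sprintf("isoform table: %d rows over %d isoforms\n", nrow(tab),
            length(setdiff(unique(tab$isoform), "unassigned"))))

top <- top_expressed(tpms, n = 30, unitags = map$unitag,
                     annotations = map)
write_report(top, file.path(TABLE_DIR, "top_expressed.tsv"), digits = 0)
cat(sprintf("top expressed: %d family unitags, leader %s at %d tpm max\n",
            nrow(top), top$unitag[1],
            max(top[1, c("SD24T", "SDTC", "SD24S", "SDSC")])))

div <- suppressWarnings(
  divergence_table(results$tolerant, results$sensitive,
                   annotations = map))
write_report(div, file.path(TABLE_DIR, "divergence.tsv"))
s <- attr(div, "summary")
cat(sprintf("divergence: %d significant unitags; UR->DR %d, DR->UR %d\n",
            nrow(div), s["UR", "DR"], s["DR", "UR"]))

mk <- candidate_markers(tab, divergence = div, isoform_map = map)
write_report(mk, file.path(TABLE_DIR, "candidate_markers.tsv"))
cat(sprintf("candidate markers: %d (%d divergent)\n", nrow(mk),
            sum(mk$pattern == "divergent")))
if (any(mk$pattern == "divergent"))
  print(mk[mk$pattern == "divergent", ])

mat <- fc_matrix(results, map)
write_report(mat, file.path(TABLE_DIR, "fc_matrix.tsv"))
cat(sprintf("fc matrix: %d isoforms x %d contrasts\n", nrow(mat),
            ncol(mat)))
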