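#!/usr/bin/env Rscript
# Stage 2: per-library singleton exclusion and tags-per-million
# normalisation. The normalisation base stays the sequenced total (N), not
# the post-exclusion sum.

source(file.path("analysis", "00_config.R"))

libs <- list()
for (id in LIB_IDS) {
  lib <- read_library(file.path(DATA_DIR, paste0(id, "_tags.tsv")),
                      id = id, bulk = LIB_BULK[[id]],
                      treatment = LIB_TREAT[[id]])
  before <- length(lib$counts)
  lib <- exclude_singletons(lib)
  cat(sprintf("%s: %d unitags sequenced, %d singletons excluded, %d kept\n",
              id, before, before - length(lib$counts),
              length(lib$counts)))
  write_library(lib, file.path(DATA_DIR, paste0(id, "_filtered.tsv")))
  libs[[id]] <- lib
}

tpms <- tpm_table(libs)
write_report(tpms, file.path(TABLE_DIR, "tpm_table.tsv"))
cat(sprintf("tpm table: %d unitags x %d libraries -> %s\n",
            nrow(tpms), length(libs),
            file.path(TABLE_DIR, "tpm_table.tsv")))
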