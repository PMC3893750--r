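#!/usr/bin/env Rscript
# Stage 3: Audic-Claverie exact-test contrasts (stress vs control within
# each bulk) with signed fold changes; raw P thresholded at 0.05.

source(file.path("analysis", "00_config.R"))

libs <- lapply(LIB_IDS, function(id)
  exclude_singletons(read_library(
    file.path(DATA_DIR, paste0(id, "_tags.tsv")),
    id = id, bulk = LIB_BULK[[id]], treatment = LIB_TREAT[[id]])))
names(libs) <- LIB_IDS

contrasts <- list(
  tolerant = contrast_spec("tolerant", "SD24T", "SDTC", alpha = 0.05),
  sensitive = contrast_spec("sensitive", "SD24S", "SDSC", alpha = 0.05))

truth <- read_truth(file.path(DATA_DIR, "ground_truth.tsv"))
for (cn in names(contrasts)) {
  res <- run_contrast(contrasts[[cn]], libs)
  write_report(res, file.path(TABLE_DIR, paste0("contrast_", cn, ".tsv")))
  cat(sprintf("%s (%s vs %s): %d unitags, %d UR, %d DR\n", cn,
              contrasts[[cn]]$numerator, contrasts[[cn]]$denominator,
              nrow(res), sum(res$call == "UR"), sum(res$call == "DR")))
  # planted truth recovery at a glance
  col <- paste0("status_", cn)
  planted <- truth[truth[[col]] != "ns", c("unitag", col)]
  if (nrow(planted)) {
    m <- res[match(planted$unitag, res$unitag), ]
    cat(sprintf("  planted %s recovery: %d of %d called as planted\n",
                cn, sum(m$call == planted[[col]], na.rm = TRUE),
                nrow(planted)))
  }
}
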