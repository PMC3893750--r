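#!/usr/bin/env Rscript
# Stage 1: simulate the study -- an EST reference (aquaporin + background
# records) and four ~200k-tag bulked libraries with planted expression
# patterns. Everything downstream works only from the files written here.

source(file.path("analysis", "00_config.R"))

cfg <- study_config()
ref <- generate_reference(cfg)
cat(sprintf("reference: %d ESTs (%d aquaporin-annotated, %d isoforms)\n",
            nrow(ref), sum(!is.na(ref$isoform)),
            length(unique(na.omit(ref$isoform)))))

base <- generate_libraries(cfg, ref)
effects <- planted_effects_for(base$truth)
gen <- generate_libraries(cfg, ref, effects = effects)

write_reference(ref, file.path(DATA_DIR, "reference.fasta"),
                file.path(DATA_DIR, "reference_annotations.tsv"))
for (id in LIB_IDS)
  write_library(gen$libraries[[id]],
                file.path(DATA_DIR, paste0(id, "_tags.tsv")))
write_truth(gen$truth, file.path(DATA_DIR, "ground_truth.tsv"))
write.table(effects, file.path(DATA_DIR, "planted_effects.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("libraries: %s tags each; %d unitags in the universe\n",
            paste(unique(vapply(gen$libraries, `[[`, numeric(1), "N")),
                  collapse = "/"),
            nrow(gen$truth)))
cat(sprintf("planted: %d effects (%d on aquaporin unitags)\n",
            nrow(effects),
            sum(effects$unitag %in%
                  gen$truth$unitag[!is.na(gen$truth$isoform)])))
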