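# Shared settings for the analysis scripts: one seeded synthetic study
# emulating the four bulked sugarcane root libraries, with planted
# expression patterns mirroring the marker-grade behaviours the pipeline
# is meant to surface (a divergent PIP1-1-like unitag, exclusive UR/DR
# unitags at the observed effect-size range).

library(sagetag)

SEED <- 20260920 %% 1e6          # 920: fixed study seed
DATA_DIR <- file.path("results", "data")
TABLE_DIR <- file.path("results", "tables")
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(TABLE_DIR, showWarnings = FALSE, recursive = TRUE)

study_config <- function() sim_config(seed = SEED)

# planted effects are chosen among well-expressed unitags (>= 100 tpm)
# once the base expression profile is known; see 01_simulate.R
planted_effects_for <- function(truth) {
  aq <- truth[!is.na(truth$isoform) & truth$exp_tpm_SDTC >= 100, ]
  bg <- truth[is.na(truth$isoform) & truth$exp_tpm_SDTC >= 100, ]
  stopifnot(nrow(aq) >= 3, nrow(bg) >= 4)
  aq <- aq[order(-aq$base_weight), ]
  bg <- bg[order(-bg$base_weight), ]
  rbind(
    # divergent marker pattern: up under stress in the tolerant bulk,
    # down in the sensitive bulk, same unitag (the PIP1-1-style candidate)
    data.frame(unitag = aq$unitag[1], contrast = c("tolerant", "sensitive"),
               fc = c(3.58, -4.56)),
    # exclusively up- (tolerant) and down-regulated (sensitive) isoform
    # unitags at the moderate effect sizes seen in the study
    data.frame(unitag = aq$unitag[2:3], contrast = c("tolerant", "sensitive"),
               fc = c(2.4, -1.7)),
    # background (non-family) regulation, invisible to the family reports
    data.frame(unitag = bg$unitag[1:4],
               contrast = c("tolerant", "tolerant", "sensitive", "sensitive"),
               fc = c(3.6, -2.4, 1.7, -3.6)))
}

LIB_IDS <- c("SD24T", "SDTC", "SD24S", "SDSC")
LIB_BULK <- c(SD24T = "tolerant", SDTC = "tolerant",
              SD24S = "sensitive", SDSC = "sensitive")
LIB_TREAT <- c(SD24T = "stress", SDTC = "control",
               SD24S = "stress", SDSC = "control")
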