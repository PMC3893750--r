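test_that("config validation rejects impossible study designs", {
  expect_error(sim_config(library_sizes = c(SD24T = 0, SDTC = 1e4,
                                            SD24S = 1e4, SDSC = 1e4)),
               "positive")
  expect_error(sim_config(planted_effects = data.frame(
    unitag = "CATG", contrast = "tolerant", fc = 0)), "non-zero")
  expect_error(sim_config(est_length = c(10, 20)), "26-bp")
  expect_error(sim_config(planted_effects = data.frame(
    unitag = "CATG", contrast = "upstream", fc = 2)), "contrast")
})

test_that("every reference record yields an extractable, unique 26-bp tag", {
  ref <- tiny_reference()
  tags <- extract_tag(ref$sequence)
  expect_false(any(is.na(tags)))
  expect_true(all(is_valid <- nchar(tags) == 26 &
                    startsWith(tags, "CATG")))
  expect_equal(anyDuplicated(tags), 0L)
})

test_that("aquaporin annotations parse and background records never match", {
  ref <- tiny_reference()
  aq <- !is.na(ref$isoform)
  mined <- mine_family(ref)
  expect_true(all(mined$matched[aq]))
  expect_false(any(mined$matched[!aq]))
  # records flagged through the annotation route carry a parseable label
  by_ann <- mined$source %in% c("annotation", "both")
  expect_gt(sum(by_ann), 0)
  for (a in ref$annotation[by_ann]) {
    p <- parse_isoform(a)
    expect_false(is.null(p))
    expect_true(p$subfamily %in% c("PIP", "TIP", "NIP", "SIP"))
    expect_equal(p$label,
                 ref$isoform[match(a, ref$annotation)])
  }
  # poorly annotated family records are reachable only through GO
  expect_gt(sum(aq & mined$source == "go"), 0)
  # no aquaporins configured -> nothing matches the family keywords
  none <- generate_reference(tiny_sim_config(n_aquaporin_isoforms = 0))
  expect_false(any(mine_family(none)$matched))
})

test_that("library totals hit the configured sizes exactly", {
  cfg <- tiny_sim_config()
  gen <- generate_libraries(cfg, generate_reference(cfg))
  expect_equal(unname(vapply(gen$libraries,
                             function(l) sum(l$counts), numeric(1))),
               unname(cfg$library_sizes))
  expect_equal(unname(vapply(gen$libraries, `[[`, numeric(1), "N")),
               unname(cfg$library_sizes))
})

test_that("fixed seed makes generated artifacts byte-identical", {
  cfg <- tiny_sim_config(seed = 99)
  ref1 <- generate_reference(cfg)
  ref2 <- generate_reference(cfg)
  expect_identical(ref1, ref2)
  g1 <- generate_libraries(cfg, ref1)
  g2 <- generate_libraries(cfg, ref2)
  expect_identical(g1, g2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_library(g1$libraries$SD24T, f1)
  write_library(g2$libraries$SD24T, f2)
  expect_identical(readLines(f1), readLines(f2))
  a1 <- withr::local_tempfile(fileext = ".fasta")
  a2 <- withr::local_tempfile(fileext = ".fasta")
  write_reference(ref1, a1, withr::local_tempfile())
  write_reference(ref2, a2, withr::local_tempfile())
  expect_identical(readLines(a1), readLines(a2))
})

test_that("ground truth has one provenance entry per unitag and round-trips", {
  cfg <- tiny_sim_config(sister_fraction = 0.2)
  gen <- generate_libraries(cfg, generate_reference(cfg))
  truth <- gen$truth
  expect_equal(anyDuplicated(truth$unitag), 0L)
  expect_true(any(truth$sister))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$unitag, truth$unitag)
  expect_equal(back$base_weight, truth$base_weight)    # lossless
  expect_equal(back$exp_tpm_SD24T, truth$exp_tpm_SD24T)
})

test_that("sister tags anchor their parent EST at the same offset", {
  cfg <- tiny_sim_config(sister_fraction = 0.3)
  ref <- generate_reference(cfg)
  truth <- expression_profile(cfg, ref)
  sis <- truth[truth$sister, ][1, ]
  hits <- anchor(sis$unitag, ref[ref$id == sis$est, ],
                 mode = "one-mismatch")
  expect_true(any(hits$start == sis$offset & hits$mismatches == 1L))
})

test_that("planted effects shift expected tpm in the stressed library only", {
  cfg <- tiny_sim_config()
  ref <- generate_reference(cfg)
  base <- generate_libraries(cfg, ref)
  u <- base$truth$unitag[which.min(abs(base$truth$base_weight - 100))]
  eff <- data.frame(unitag = u, contrast = "tolerant", fc = 3.58)
  gen <- generate_libraries(cfg, ref, effects = eff)
  i <- match(u, gen$truth$unitag)
  expect_equal(gen$truth$status_tolerant[i], "UR")
  expect_gt(gen$truth$exp_tpm_SD24T[i] / gen$truth$exp_tpm_SDTC[i], 3.4)
  expect_equal(gen$truth$exp_tpm_SD24S[i], gen$truth$exp_tpm_SDSC[i],
               tolerance = 1e-12)
  expect_error(
    generate_libraries(cfg, ref, effects = data.frame(
      unitag = "CATGAAAAAAAAAAAAAAAAAAAAAA", contrast = "tolerant",
      fc = 2)),
    "unknown unitag")
})

test_that("forced singletons are planted per library and are rare unitags", {
  cfg <- tiny_sim_config(singleton_fraction = 0.05)
  gen <- generate_libraries(cfg, generate_reference(cfg))
  for (id in names(gen$libraries)) {
    flag <- gen$truth[[paste0("single_", id)]]
    expect_gt(sum(flag), 0)
    counts <- gen$libraries[[id]]$counts[gen$truth$unitag[flag]]
    expect_true(all(counts == 1L))
    expect_true(all(gen$truth[[paste0("exp_tpm_", id)]][flag] *
                      gen$libraries[[id]]$N / 1e6 < 2))
  }
  # a singleton in one library may persist with count > 1 in another
  lib24 <- gen$libraries$SD24T
  singles24 <- names(lib24$counts)[lib24$counts == 1L]
  other <- gen$libraries$SDTC$counts[singles24]
  expect_true(any(!is.na(other) & other > 1))
})

test_that("empirical mean tpm converges to the configured expectation", {
  cfg <- tiny_sim_config(singleton_fraction = 0, dispersion = 0.002)
  ref <- generate_reference(cfg)
  truth <- NULL
  reps <- 40
  acc <- NULL
  for (r in seq_len(reps)) {
    gen <- generate_libraries(cfg, ref, replicate = r)
    truth <- gen$truth
    tpm <- normalize_tpm(gen$libraries$SDTC)[truth$unitag]
    tpm[is.na(tpm)] <- 0
    acc <- if (is.null(acc)) unname(tpm) else acc + unname(tpm)
  }
  mean_tpm <- acc / reps
  mu <- truth$exp_tpm_SDTC
  # per-unitag sampling se of the mean over replicates (Poisson + gamma)
  n <- cfg$library_sizes[["SDTC"]]
  se <- sqrt((mu * 1e6 / n + cfg$dispersion * mu^2) / reps)
  frac_in <- mean(abs(mean_tpm - mu) <= 3 * pmax(se, 1e-9))
  expect_gt(frac_in, 0.95)
})
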