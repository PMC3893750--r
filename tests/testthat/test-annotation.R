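mini_reference <- function(seqs, dbs = NULL, anns = NULL, gos = NULL) {
  n <- length(seqs)
  est_reference(sprintf("EST%03d", seq_len(n)),
                if (is.null(dbs)) rep("SoGI", n) else dbs,
                rep("Saccharum officinarum", n),
                if (is.null(anns)) rep("aquaporin PIP2-1", n) else anns,
                if (is.null(gos)) rep("", n) else gos,
                seqs)
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

test_that("anchoring accepts exactly the published alignment rules", {
  set.seed(601)
  u <- random_unitag()
  flank <- function(core) paste0(random_dna(15), core, random_dna(15))
  # full containment: m = 26, score 52
  ref <- mini_reference(flank(u))
  hits <- anchor(u, ref)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$m, 26L)
  expect_equal(hits$score, 52L)
  # first 21 nt then divergence: m = 21, score 42
  part <- paste0(substr(u, 1, 21),
                 chartr("ACGT", "GTAC", substr(u, 22, 22)))
  h21 <- anchor(u, mini_reference(flank(part)))
  expect_equal(h21$m, 21L)
  expect_equal(h21$score, 42L)
  # only 20 nt of the prefix: rejected
  part20 <- paste0(substr(u, 1, 20),
                   chartr("ACGT", "GTAC", substr(u, 21, 21)))
  expect_equal(nrow(anchor(u, mini_reference(flank(part20)))), 0L)
  # reverse complement: never reported (plus/plus only)
  expect_equal(nrow(anchor(u, mini_reference(flank(revcomp(u))))), 0L)
  expect_equal(nrow(anchor(u, mini_reference(flank(revcomp(u))),
                           mode = "one-mismatch")), 0L)
})

test_that("one-mismatch mode protects the 5' CATG", {
  set.seed(602)
  u <- random_unitag()
  flank <- function(core) paste0(random_dna(10), core, random_dna(10))
  mut <- function(s, i) {
    substr(s, i, i) <- chartr("ACGT", "GTAC", substr(s, i, i)); s
  }
  inside <- anchor(u, mini_reference(flank(mut(u, 12))),
                   mode = "one-mismatch")
  expect_equal(inside$mismatches, 1L)
  expect_equal(inside$m, 26L)
  # substitution at position 2 falls inside CATG: no hit
  expect_equal(nrow(anchor(u, mini_reference(flank(mut(u, 2))),
                           mode = "one-mismatch")), 0L)
  # two substitutions: no hit
  expect_equal(nrow(anchor(u, mini_reference(flank(mut(mut(u, 12), 20))),
                           mode = "one-mismatch")), 0L)
})

test_that("anchor agrees with the brute-force scan on fuzzed cases", {
  set.seed(603)
  for (i in 1:300) {
    u <- random_unitag()
    s <- random_dna(sample(40:150, 1))
    # half the time embed a (possibly corrupted) copy to create hits
    if (i %% 2 == 0) {
      core <- u
      if (i %% 4 == 0) {
        p <- sample(1:26, 1)
        substr(core, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      cut <- sample(18:26, 1)
      at <- sample(1:(nchar(s) - cut), 1)
      s <- paste0(substr(s, 1, at - 1), substr(core, 1, cut),
                  substr(s, at + cut, nchar(s)))
    }
    ref <- mini_reference(s)
    for (mode in c("exact-prefix", "one-mismatch")) {
      got <- anchor(u, ref, mode = mode)
      want <- oracle_anchor(u, s, mode)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        o1 <- order(got$start); o2 <- order(want$start)
        expect_equal(got$start[o1], want$start[o2])
        expect_equal(got$m[o1], want$m[o2])
        expect_equal(got$mismatches[o1], want$mismatches[o2])
      }
    }
  }
})

test_that("every reported hit satisfies the acceptance invariants", {
  set.seed(604)
  ref <- tiny_reference()
  tags <- extract_tag(ref$sequence)
  hits <- anchor_all(sample(tags, 25), ref[sample.int(nrow(ref), 60), ])
  expect_true(all(hits$m >= 21 & hits$m <= 26))
  expect_true(all(hits$mismatches <= 1))
  expect_true(all(hits$score[hits$mismatches == 0] ==
                    2 * hits$m[hits$mismatches == 0]))
  # 5' CATG preserved at every reported offset
  for (i in seq_len(nrow(hits))) {
    s <- ref$sequence[ref$id == hits$est[i]]
    expect_equal(substr(s, hits$start[i] + 1, hits$start[i] + 4), "CATG")
  }
})

test_that("best hit prioritises sugarcane databases, then score, then id", {
  u <- random_unitag()
  hits <- data.frame(
    unitag = u, est = c("Z1", "S1", "S2", "S3"),
    database = c("ZmGI", "SoGI", "SoGI", "SoGI"),
    start = 0L, m = c(26L, 21L, 24L, 24L), mismatches = 0L,
    score = c(52L, 42L, 48L, 48L), stringsAsFactors = FALSE)
  ref <- est_reference(c("Z1", "S1", "S2", "S3"),
                       c("ZmGI", "SoGI", "SoGI", "SoGI"),
                       "sp", c("aquaporin PIP1-1", "aquaporin PIP1-2",
                               "aquaporin PIP1-3", "aquaporin PIP1-3"),
                       "", strrep("A", 30))
  # sugarcane database outranks a higher-scoring maize hit
  expect_equal(best_hit(hits, ref)$est, "S2")
  # equal score ties break lexicographically
  expect_equal(best_hit(hits[3:4, ], ref)$est, "S2")
  # single hit wins trivially; permutations never change the winner
  expect_equal(best_hit(hits[1, , drop = FALSE], ref)$est, "Z1")
  set.seed(605)
  for (i in 1:10) {
    perm <- hits[sample.int(nrow(hits)), ]
    expect_equal(best_hit(perm, ref)$est, "S2")
  }
  # inadequate annotation demotes a hit below adequately annotated ones
  ref2 <- ref; ref2$annotation[c(2, 3, 4)] <- "unknown protein"
  expect_equal(best_hit(hits, ref2)$est, "Z1")
  expect_null(best_hit(hits[0, ], ref))
})

test_that("family mining follows keyword and GO routes with token boundaries", {
  ref <- mini_reference(
    rep(strrep("A", 30), 5),
    anns = c("plasma membrane intrinsic protein 2-4",
             "unknown protein", "pipecolate oxidase",
             "putative PIP2 aquaporin", "PIPELINE related protein"),
    gos = c("", "water transport", "", "", ""))
  got <- mine_family(ref)
  expect_equal(got$matched, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(got$source[1:2], c("annotation", "go"))
  expect_error(mine_family(ref, keywords = character()), "empty")
})

test_that("family mining is monotone in the keyword list", {
  set.seed(606)
  ref <- tiny_reference()
  base_kw <- default_family_keywords()
  m1 <- mine_family(ref, keywords = base_kw[1:3])
  m2 <- mine_family(ref, keywords = base_kw)
  expect_true(all(m2$matched[m1$matched]))
})

test_that("isoform parsing normalises separators and keeps dual labels", {
  p <- parse_isoform("aquaporin PIP2-4", species = "So")
  expect_equal(p[c("subfamily", "label", "species")],
               list(subfamily = "PIP", label = "PIP2-4", species = "So"))
  expect_equal(parse_isoform("tonoplast intrinsic protein TIP1;1")$label,
               "TIP1-1")
  expect_equal(parse_isoform("So aquaporin PIP1-3/PIP1-4")$label,
               "PIP1-3/PIP1-4")
  expect_equal(parse_isoform("NIP 3-1 nodulin-like")$label, "NIP3-1")
  expect_equal(parse_isoform("SIP1 small basic protein")$label, "SIP1")
  expect_null(parse_isoform("water channel protein"))
  expect_null(parse_isoform(""))
})

test_that("specificity tally reproduces the published percentage arithmetic", {
  expect_equal(tally_percent(c(263, 19, 7), 289), c(91, 7, 2))
  # the published figure truncates 97.107 to 97.10; agree to the printed
  # precision
  expect_lt(abs(tally_percent(470, 484, digits = 2) - 97.10), 0.011)
  calls <- c(
    replicate(10, list("PIP2-4")),                      # isoform-specific
    list(c("PIP2-1", "PIP2-4")),                        # subclass PIP2
    list(c("PIP1-1", "TIP1-1")))                        # nonspecific
  names(calls) <- sprintf("u%02d", seq_along(calls))
  tl <- specificity_tally(calls)
  expect_equal(unname(tl$counts), c(10, 1, 1))
  expect_equal(unname(tl$percent), c(83, 8, 8))
  expect_equal(tl$n, 12)
  one <- specificity_tally(list(u1 = "TIP2-2"))
  expect_equal(unname(one$counts["isoform"]), 1)
})
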