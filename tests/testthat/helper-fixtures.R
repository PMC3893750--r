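# Shared fixtures and independent oracles.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_unitag <- function() paste0("CATG", random_dna(22))

# A config small enough for unit tests (the defaults emulate the full
# scaled-down study and are exercised in the acceptance suite).
tiny_sim_config <- function(seed = 11, n_background_ests = 300,
                            n_aquaporin_isoforms = 8, ...) {
  sim_config(n_background_ests = n_background_ests,
             n_aquaporin_isoforms = n_aquaporin_isoforms,
             library_sizes = c(SD24T = 2e4, SDTC = 2e4,
                               SD24S = 2e4, SDSC = 2e4),
             seed = seed, ...)
}

tiny_reference <- function(seed = 11, ...) {
  generate_reference(tiny_sim_config(seed = seed, ...))
}

# Independent oracle for ac_pvalue: the conditional distribution of the
# second count given the first is negative binomial with size x+1 and
# success probability N1/(N1+N2), so every tail comes from R's
# incomplete-beta implementation; the bilateral (symmetric) combination
# mirrors the package definition through this separate numerical route.
oracle_ac <- function(x, y, n1, n2, sided = "two") {
  pA <- n1 / (n1 + n2)          # conditioning on x
  pB <- n2 / (n1 + n2)          # conditioning on y, totals swapped
  loA <- stats::pnbinom(y, size = x + 1, prob = pA)
  upA <- stats::pnbinom(y - 1, size = x + 1, prob = pA,
                        lower.tail = FALSE)
  loB <- stats::pnbinom(x, size = y + 1, prob = pB)
  upB <- stats::pnbinom(x - 1, size = y + 1, prob = pB,
                        lower.tail = FALSE)
  if (y / n2 >= x / n1) {
    dev <- max(upA, loB); comp <- max(loA, upB)
  } else {
    dev <- max(loA, upB); comp <- max(upA, loB)
  }
  if (sided == "one") dev else min(1, 2 * min(dev, comp))
}

# Independent oracle for anchor(): brute-force scan over every offset and
# every prefix length / mismatch pattern.
oracle_anchor <- function(unitag, est_seq, mode) {
  tag <- strsplit(unitag, "")[[1]]
  L <- nchar(est_seq)
  s <- strsplit(est_seq, "")[[1]]
  hits <- list()
  for (p in seq_len(L)) {
    if (mode == "exact-prefix") {
      best_m <- 0L
      for (m in 21:26) {
        if (p + m - 1L > L) break
        if (all(s[p:(p + m - 1L)] == tag[1:m])) best_m <- m else break
      }
      if (best_m >= 21L)
        hits[[length(hits) + 1L]] <-
          data.frame(start = p - 1L, m = best_m, mismatches = 0L)
    } else {
      if (p + 25L > L) next
      d <- which(s[p:(p + 25L)] != tag)
      if (length(d) <= 1L && all(d >= 5L))
        hits[[length(hits) + 1L]] <-
          data.frame(start = p - 1L, m = 26L, mismatches = length(d))
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), m = integer(),
                      mismatches = integer()))
  do.call(rbind, hits)
}

# Two exact-test contrasts (stress vs control per bulk) on a generated run
run_both_contrasts <- function(gen, alpha = 0.05) {
  libs <- lapply(gen$libraries, exclude_singletons)
  list(tolerant = run_contrast(contrast_spec("tolerant", "SD24T", "SDTC",
                                             alpha), libs),
       sensitive = run_contrast(contrast_spec("sensitive", "SD24S", "SDSC",
                                              alpha), libs))
}
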