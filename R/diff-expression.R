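#' Audic-Claverie exact test for two tag counts
#'
#' Given `x` occurrences of a unitag among `N1` tags in one library and `y`
#' among `N2` in another, the conditional distribution of the second count
#' given the first (under equal underlying frequency) is
#' \deqn{p(k \mid x) = \left(\frac{N2}{N1}\right)^k
#'   \frac{(x+k)!}{x!\,k!\,(1+N2/N1)^{x+k+1}}}
#' The one-sided p-value is the tail sum of `p(k|x)` from `y` upward when
#' `y/N2 >= x/N1`, and from 0 to `y` otherwise; the two-sided p-value
#' doubles the smaller tail, capped at 1. Because the conditional form is
#' not symmetric in the two libraries, each tail is evaluated in both
#' orientations (conditioning on `x` and, with the totals swapped, on `y`)
#' and the more conservative of the two is kept, making
#' `ac_pvalue(x, y, N1, N2) == ac_pvalue(y, x, N2, N1)` hold exactly.
#' All terms are evaluated in log space via `lgamma`; the infinite upper
#' tail is summed adaptively in blocks with compensated accumulation until
#' additional terms are negligible, so small p-values keep full relative
#' precision (no `1 - lower` cancellation).
#'
#' @param x,y Non-negative observed counts (vectors, recycled).
#' @param n1,n2 Positive library totals (scalars).
#' @param sided `"two"` (default) or `"one"`.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
ac_pvalue <- function(x, y, n1, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(n1) != 1L || length(n2) != 1L || n1 <= 0 || n2 <= 0)
    stop("n1 and n2 must be positive scalars")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  nn <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), nn)
  y <- rep_len(as.numeric(y), nn)
  key <- paste(x, y)
  uniq <- !duplicated(key)
  pu <- vapply(which(uniq), function(i) {
    .ac_pvalue1(x[i], y[i], n1, n2, sided)
  }, numeric(1))
  unname(pu[match(key, key[uniq])])
}

# log p(k | x) for the AC conditional distribution, vectorised over k
.ac_logpk <- function(k, x, logr, log1pr) {
  k * logr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1pr
}

# P(K <= y): finite sum of positive terms (ascending k keeps the sum
# well-conditioned; terms are exact to lgamma precision)
.ac_lower <- function(x, y, logr, log1pr) {
  min(1, sum(exp(.ac_logpk(0:y, x, logr, log1pr))))
}

# P(K >= y): adaptive block summation of the infinite tail with Neumaier
# compensation across blocks; summing the small tail directly (instead of
# 1 - lower) preserves full relative precision for tiny p-values
.ac_upper <- function(x, y, logr, log1pr) {
  total <- 0; comp <- 0
  k0 <- y
  block <- 64L
  repeat {
    terms <- exp(.ac_logpk(k0:(k0 + block - 1L), x, logr, log1pr))
    b <- sum(terms)
    t <- total + b
    comp <- comp + if (abs(total) >= abs(b)) (total - t) + b
                   else (b - t) + total
    total <- t
    last <- terms[block]
    k0 <- k0 + block
    # stop once past the mode and the last term can no longer matter
    decreasing <- last < terms[1L] || last == 0
    if (decreasing && (last * block < total * 1e-16 || last == 0)) break
    if (k0 > y + 1e7) stop("tail summation failed to converge")
    block <- min(2L * block, 1024L)
  }
  min(1, total + comp)
}

.ac_pvalue1 <- function(x, y, n1, n2, sided) {
  # bilateral evaluation: condition on x (tail over the second count) and
  # on y (tail over the first), and keep the more conservative tail of the
  # two orientations; this makes the test exactly symmetric in the library
  # pair, which the one-directional conditional form is not
  rA <- n2 / n1; logrA <- log(rA); log1prA <- log1p(rA)
  rB <- n1 / n2; logrB <- log(rB); log1prB <- log1p(rB)
  if (y / n2 >= x / n1) {
    dev <- max(.ac_upper(x, y, logrA, log1prA),
               .ac_lower(y, x, logrB, log1prB))
    if (sided == "one") return(dev)
    comp <- max(.ac_lower(x, y, logrA, log1prA),
                .ac_upper(y, x, logrB, log1prB))
  } else {
    dev <- max(.ac_lower(x, y, logrA, log1prA),
               .ac_upper(y, x, logrB, log1prB))
    if (sided == "one") return(dev)
    comp <- max(.ac_upper(x, y, logrA, log1prA),
                .ac_lower(y, x, logrB, log1prB))
  }
  min(1, 2 * min(dev, comp))
}

#' Signed fold change between two tpm values
#'
#' The fold change of the stressed library over its control, with the
#' convention that ratios below 1 are reported as the negative reciprocal so
#' that `|FC| >= 1` always. Zero frequencies are replaced by a pseudo
#' frequency of 1 tpm before the ratio is formed, so a tag absent from the
#' control but at 496.29 tpm under stress reports FC 496.29.
#'
#' @param tpm1 tpm in the stressed (numerator) library; vectorised.
#' @param tpm2 tpm in the control (denominator) library; vectorised.
#' @param floor Pseudo-frequency replacing values below it (default 1 tpm).
#' @return Numeric vector of signed fold changes, full precision (round to
#'   2 decimals only for display).
#' @export
signed_fc <- function(tpm1, tpm2, floor = 1) {
  if (any(tpm1 < 0) || any(tpm2 < 0)) stop("tpm values must be non-negative")
  z1 <- pmax(tpm1, floor)
  z2 <- pmax(tpm2, floor)
  ifelse(z1 >= z2, z1 / z2, -z2 / z1)
}

#' Define a library contrast
#'
#' @param name Contrast label, e.g. `"SD24T vs SDTC"`.
#' @param numerator Id of the stressed / first-named library.
#' @param denominator Id of the control / second-named library.
#' @param alpha Significance level for the UR/DR call (raw p-value
#'   threshold; the classification deliberately applies no multiple-testing
#'   correction).
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, numerator, denominator, alpha = 0.05) {
  if (identical(numerator, denominator))
    stop("numerator and denominator libraries must differ")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, alpha = alpha),
            class = "contrast_spec")
}

#' Classify unitags of a library pair as UR / DR / ns
#'
#' Runs the Audic-Claverie exact test and the signed fold change over every
#' unitag present (count > 0) in at least one of the two libraries
#' (singleton exclusion is expected to have been applied already). A unitag
#' is up-regulated (UR) when `P < alpha` and `FC > 1`, down-regulated (DR)
#' when `P < alpha` and `FC < -1`, otherwise not significant (ns). Raw
#' p-values are thresholded; no multiplicity correction is applied.
#'
#' @param spec A [contrast_spec].
#' @param libraries Named list of [tag_library] objects containing the two
#'   contrasted ids.
#' @param sided Tail mode passed to [ac_pvalue()].
#' @return Data frame with columns `unitag`, `x`, `y`, `N1`, `N2`, `tpm1`,
#'   `tpm2`, `FC`, `P`, `call`, ordered by unitag; the contrast name is
#'   attached as attribute `"contrast"`.
#' @export
run_contrast <- function(spec, libraries, sided = "two") {
  stopifnot(inherits(spec, "contrast_spec"))
  if (is.null(names(libraries)))
    names(libraries) <- vapply(libraries, `[[`, character(1), "id")
  for (lib in c(spec$numerator, spec$denominator))
    if (!lib %in% names(libraries))
      stop(sprintf("unknown library id '%s'", lib))
  lib1 <- libraries[[spec$numerator]]
  lib2 <- libraries[[spec$denominator]]
  unitags <- sort(union(names(lib1$counts)[lib1$counts > 0],
                        names(lib2$counts)[lib2$counts > 0]))
  x <- unname(ifelse(is.na(lib1$counts[unitags]), 0L, lib1$counts[unitags]))
  y <- unname(ifelse(is.na(lib2$counts[unitags]), 0L, lib2$counts[unitags]))
  tpm1 <- x * 1e6 / lib1$N
  tpm2 <- y * 1e6 / lib2$N
  fc <- signed_fc(tpm1, tpm2)
  p <- ac_pvalue(x, y, lib1$N, lib2$N, sided = sided)
  call <- rep("ns", length(unitags))
  call[p < spec$alpha & fc > 1] <- "UR"
  call[p < spec$alpha & fc < -1] <- "DR"
  res <- data.frame(unitag = unitags, x = x, y = y,
                    N1 = lib1$N, N2 = lib2$N,
                    tpm1 = tpm1, tpm2 = tpm2,
                    FC = fc, P = p, call = call,
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- spec$name
  res
}
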