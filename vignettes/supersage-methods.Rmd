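---
title: "Digital expression profiling of HT-SuperSAGE tag libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital expression profiling of HT-SuperSAGE tag libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagetag)
```

## The measurement

HT-SuperSAGE measures transcript abundance by sequencing 26-bp tags
anchored at the 3'-most NlaIII recognition site (CATG) of each transcript.
A *unitag* is a distinct tag sequence; its per-library count is the
expression measurement. `sagetag` implements the complete analysis path
for such libraries: tag extraction, counting, filtering, normalisation,
exact-test contrasts, tag-to-EST anchoring, gene-family mining, and
isoform-level reporting. The motivating study design is four bulked
sugarcane root libraries — drought-tolerant and drought-sensitive genotype
pools, each under 24 h root dehydration and under daily irrigation
(SD24T/SDTC and SD24S/SDSC) — profiled for the aquaporin (major intrinsic
protein) family and its four higher-plant subfamilies PIP, TIP, NIP and
SIP.

`extract_tag()` returns the 26-mer at the 3'-most CATG with at least 22 nt
downstream. Real libraries also contain tags from internal CATG sites left
by partial NlaIII digestion; `partial = TRUE` models this by emitting every
qualifying site. It is off by default because multi-site tags are an
artifact to be studied, not the canonical measurement. Windows containing
non-ACGT characters are skipped (never corrected), falling back to the
next 3'-most clean site.

Counting (`count_tags()`) records `N`, the sequenced total, separately
from the retained count map. Singletons — unitags seen exactly once in a
library — are unreliable and removed per library (`exclude_singletons()`);
a singleton in one library keeps its count in another. Normalisation to
tags per million (`normalize_tpm()`) uses `tpm = count * 1e6 / N` with `N`
the *pre-exclusion* sequenced total: library sizes are reported as
sequenced totals and "per million of the library" reads most naturally as
per million sequenced tags. This is an assumption — whether the original
analysis normalised before or after singlet exclusion is not documented —
and because excluded singleton mass is below 2% of a realistic library,
the two choices differ by under 2% on every tpm value.

## The exact test and the signed fold change

For a unitag with counts `x` and `y` in libraries of totals `N1` and `N2`,
the Audic–Claverie conditional distribution of the second count given the
first (under a common underlying frequency and a flat prior on it) is

$$p(k \mid x) = \left(\frac{N_2}{N_1}\right)^{k}
  \frac{(x+k)!}{x!\,k!\,\left(1 + N_2/N_1\right)^{x+k+1}},$$

a negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$. The one-sided p-value is the tail sum from `y` upward
when `y/N2 >= x/N1` and from 0 to `y` otherwise; the two-sided p-value
doubles the smaller tail and caps at 1. Doubling is the conservative
standard choice, and a two-sided decision is what a single threshold
producing both UR and DR calls implies.

Two numerical points matter:

* **Tails are summed in log space** via `lgamma`, and the infinite upper
  tail is summed directly — adaptively, in growing blocks, with
  compensated accumulation — rather than as `1 - lower`. Computing the
  small tail directly preserves full relative precision for p-values far
  below machine epsilon's neighbourhood of 1 (the package reproduces the
  closed form $\sum_{k\ge 20} 2^{-(k+1)} = 2^{-20}$ exactly to 1e-12).
* **The conditional form is not symmetric in the two libraries**: termwise
  it changes by a factor $N_1/N_2$ under $(x, N_1) \leftrightarrow
  (y, N_2)$, and tail p-values can differ by a factor of about two for
  very unequal totals. A digital-expression classifier should not change
  its verdict when the pair is merely written in the other order, so
  `ac_pvalue()` evaluates every tail in both orientations — conditioning
  on `x`, and with the totals swapped on `y` — and keeps the more
  conservative of the two. The maximum of two valid p-values is itself a
  valid p-value, the result is exactly symmetric, and UR/DR calls flip
  exactly under contrast reversal.

The fold change between stressed and control tpm follows the
negative-reciprocal convention: `FC = tpm1/tpm2` when `tpm1 >= tpm2`, else
`-tpm2/tpm1`, so `|FC| >= 1` always. Frequencies below 1 tpm are replaced
by a pseudo-frequency of 1 tpm before the ratio: a tag at 496.29 tpm under
stress and absent from the control reports FC 496.29, matching the
published convention (a zero-control fold change printed equal to the
stressed tpm). FC is computed at full precision; the two-decimal rounding
seen in report tables is display-only.

Calls are UR when `P < alpha` and `FC > 1`, DR when `P < alpha` and
`FC < -1`, else ns, with `alpha = 0.05` on *raw* p-values — deliberately no
multiple-testing correction, matching the original single-threshold
screening design. The unitag universe of a contrast is the union of
unitags with nonzero retained count in either library, so tags present in
only one library are still tested.

## Anchoring and family mining

Tag-to-EST anchoring models the original BLASTn acceptance rules without
running BLAST: at 21–26 nt and 100% identity the e-value filter is never
the binding constraint, and the score band 42–52 is exactly `2 * m` for a
perfect match of length `m` in 21..26. `anchor()` therefore accepts, in
`exact-prefix` mode, any exact sense-strand match of a unitag prefix of
length at least 21 (reporting the longest `m` per EST offset), and in
`one-mismatch` mode a full-length 26-nt alignment with at most one
substitution outside the 5' CATG. Reverse-complement matches are never
accepted, and the 5' CATG must be preserved in both modes. For the
one-mismatch mode the reported score is `2 * (m - mismatches)`; only the
perfect-match case has a published score to match.

`best_hit()` resolves multi-hit unitags deterministically: adequately
annotated ESTs first (a deny-pattern `unknown|hypothetical|unnamed`
operationalises "adequate annotation"), then source-database rank —
sugarcane databanks (dbEST, SoGI) ahead of progressively less related
grasses — then score, then EST id. The ranking is a total order, so the
winner is independent of input order.

Family mining (`mine_family()`) combines two routes. Long keywords
("aquaporin", "plasma membrane intrinsic protein", ...) match
case-insensitively as substrings. The four short subfamily codes match
case-sensitively with no adjacent letters (digits allowed), so `PIP2-4`
matches but `pipecolate` and `PIPELINE` do not. The GO route matches any
GO term containing "water transport". The default keyword set uses NIP —
one published keyword list prints "PIN" where its companion list prints
"NIP"; we treat that as a typographic slip, and the keyword set is
configurable. `parse_isoform()` normalises isoform labels across databank
conventions (`TIP1;1` to `TIP1-1`) and preserves dual labels such as
`PIP1-3/PIP1-4` that tags cannot distinguish.

Unitag specificity (`specificity_tally()`) classifies each anchored unitag
by whether its accepted hits agree on one isoform, only on a subfamily
group (e.g. all PIP2), or not at all — the published tally arithmetic
(263/289 = 91%, etc.) is exactly this computation.

## Reporting

`isoform_table()` counts UR/DR/ns unitags per isoform per contrast,
routing unmapped unitags to an explicit `unassigned` bucket so totals are
conserved. `top_expressed()` ranks family unitags by maximum tpm across
libraries (ties: total tpm, then unitag id). `divergence_table()` joins
the tolerant and sensitive contrasts on their common universe and keeps
unitags significant in at least one. `candidate_markers()` implements the
marker patterns: exclusive-UR/exclusive-DR (an isoform with significant
unitags in only one direction within a contrast) and divergent (UR in one
bulk's contrast and DR in the other's, via the same or different unitags).
The published candidate panel was a curated short-list; the function
implements the stated patterns, not the curation. `fc_matrix()` exports an
isoform-by-contrast matrix for heat-map rendering, using each isoform's
most extreme significant unitag and 0 where none is significant — the
matrix is the export; figure rendering is out of scope. All report
rows have deterministic sort keys, so identical inputs give byte-identical
files.

## The synthetic study

Because no tag-level archive of the original libraries is deposited, the
package ships a generator (`sim_config()`, `generate_reference()`,
`generate_libraries()`) that emulates the study design with known ground
truth. Its defaults are fixed study conditions, not tuning knobs:

* **Library sizes**: 200,000 tags each, a scaled-down stand-in for the
  published totals (2,542,552 / 1,909,543 / 2,170,998 / 2,164,222;
  available as `study_library_sizes()`).
* **Unitag density**: 18,000 background ESTs plus 42 aquaporin isoforms
  whose EST multiplicity follows a truncated geometric on 1..30, giving
  roughly 18,000 unitags — the study's density (205,975 unitags over 8.8M
  tags, about ten tags per unitag per library) reproduced at the reduced
  scale.
* **Abundance profile**: log-normal with median `base_expression = 30` tpm
  and `sdlog = 1.3`, spanning singletons to a few thousand tpm as in the
  published top-expressed table; expected tpm are renormalised to sum to
  one million per library.
* **Count model**: gamma-mixed Poisson conditioned on the exact library
  total — per library, mean-1 gamma weights with squared CV `dispersion`
  multiply the expected tpm, and the total is allocated multinomially, so
  per-library sums equal the configured sizes exactly. The default
  `dispersion = 0.002` (about 4.5% extra CV) models technical,
  resampling-level reproducibility: that is the regime the exact test
  assumes, and the generator's own null-calibration requirement (empirical
  type-I within one point of alpha) pins dispersion to this regime. The
  between-genotype variance inside a bulk is unknown, so dispersion is an
  exposed parameter for sensitivity analyses rather than an asserted
  biological value.
* **Forced singletons**: 5% of unitags are emitted with count exactly 1
  per library so the exclusion rule is always exercised; they are drawn
  only from naturally rare unitags (expected count below 2), because
  forcing an abundant unitag to a singleton in one library would fabricate
  differential expression.
* **Annotations**: aquaporin records carry `"<prefix> aquaporin
  <label>"`, a long-name variant, or (15%) an uninformative description
  with the GO term `water transport` — exercising the GO-only mining route
  the keyword search misses. Species prefixes span the nine source
  databanks (So, Ss, Sb, Zm, Os, Pv, Ta, Hv, Fa) to exercise best-hit
  prioritisation. Background annotations include deliberate negatives
  (e.g. "pipecolate oxidase") and inadequate descriptions.
* **Sister tags** (single-base variants anchoring the same EST) can be
  planted via `sister_fraction`; they are distinct unitags by definition.

Planted effects are signed fold changes (`|fc| >= 1`) multiplying the
expected tpm of the stressed library of a contrast. With a fixed seed
every artifact is byte-identical across runs.

What the generator does *not* emulate: read-level sequencing error and
adapter chemistry, EcoP15I cut-length variability, genotype-level
structure within a bulk (bulk-level only), and real sequence homology
between ESTs of one isoform (family membership is carried by annotation,
not sequence similarity). Passing tests on synthetic data therefore
demonstrate the pipeline's statistical and bookkeeping correctness under
the study design — not robustness to alignment ambiguity or sequencing
artifacts of real libraries.

## Problem sizes and verification

The test suite checks the exact test against an independent
incomplete-beta oracle (1,000 random cases, 1e-10 relative), anchoring
against a brute-force all-offsets scan (1,000 fuzzed cases in both modes),
the published fold-change and percentage arithmetic, a 50-replicate null
simulation at the default study conditions (UR+DR fraction at most 0.06 at
alpha 0.05), and a 50-replicate recovery simulation of planted effects at
the observed effect-size range (|FC| 1.7–3.6 at 100+ tpm; direction
recovery at least 90%, and the planted divergent isoform surfacing in the
candidate-marker panel). Unit tests run on a reduced universe (300
background ESTs, 20,000-tag libraries); simulation-based checks use the
full scaled-down defaults.

## Known limitations

* The exact test models resampling noise only; with biological dispersion
  between bulks it is anti-conservative, which is inherent to the original
  screening design (dispersion-based tests are an explicit non-goal).
* Raw-p thresholding at 0.05 over ~15,000 unitags implies hundreds of
  false positives by construction; the pipeline mirrors the original
  screen and leaves error-rate control to downstream validation.
* Anchoring is exact-prefix/one-mismatch string matching; it does not
  model indels or BLAST heuristics beyond the published acceptance band.
* `tpm` pseudo-frequency replacement at 1 tpm is inferred from the
  published zero-control fold changes, not documented by the original
  software.
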