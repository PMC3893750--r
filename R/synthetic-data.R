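#' Published library sizes of the four bulked root libraries
#'
#' Total sequenced 26-bp tag counts of the four HT-SuperSAGE root
#' libraries: tolerant bulk under stress (SD24T) and control (SDTC),
#' sensitive bulk under stress (SD24S) and control (SDSC). These are the
#' full-scale totals the study reports; the generator defaults use a
#' scaled-down 200,000 per library.
#'
#' @return Named numeric vector of four library totals.
#' @export
study_library_sizes <- function() {
  c(SD24T = 2542552, SDTC = 1909543, SD24S = 2170998, SDSC = 2164222)
}

LIBRARY_META <- data.frame(
  id = c("SD24T", "SDTC", "SD24S", "SDSC"),
  bulk = c("tolerant", "tolerant", "sensitive", "sensitive"),
  treatment = c("stress", "control", "stress", "control"),
  stringsAsFactors = FALSE)

DB_SPECIES <- data.frame(
  database = c("dbEST", "SoGI", "SbGI", "ZmGI", "OsGI", "PaviGI", "TaGI",
               "HvGI", "FaGI"),
  species = c("Saccharum spp.", "Saccharum officinarum",
              "Sorghum bicolor", "Zea mays", "Oryza sativa",
              "Panicum virgatum", "Triticum aestivum", "Hordeum vulgare",
              "Festuca arundinacea"),
  prefix = c("Ss", "So", "Sb", "Zm", "Os", "Pv", "Ta", "Hv", "Fa"),
  weight = c(0.20, 0.45, 0.05, 0.06, 0.06, 0.05, 0.05, 0.04, 0.04),
  stringsAsFactors = FALSE)

#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions the simulator emulates: a reference EST
#' collection containing aquaporin-annotated and background records, and
#' four bulked tag libraries (tolerant/sensitive x stress/control) with an
#' overdispersed count model, optional planted fold changes, and forced
#' per-library singletons so the exclusion rule is always exercised.
#'
#' @param n_background_ests Number of non-aquaporin reference records. The
#'   default reproduces, at the scaled-down library size, the study's
#'   unitag density of roughly ten tags per unitag per library (205,975
#'   unitags over 8.8M tags full scale scales to ~18,700 unitags at four
#'   200,000-tag libraries).
#' @param n_aquaporin_isoforms Number of distinct aquaporin isoforms
#'   (PIP/TIP/NIP/SIP labels) carried by the reference.
#' @param unitag_weights Sampling weights over 1..30 for the number of ESTs
#'   (hence unitags) per isoform; defaults to a truncated geometric, so
#'   most isoforms carry few unitags and a few carry many.
#' @param library_sizes Four positive totals named SD24T, SDTC, SD24S,
#'   SDSC. Default is the scaled-down 200,000 each;
#'   [study_library_sizes()] gives the full-scale totals.
#' @param planted_effects `NULL` or a data frame with columns `unitag`,
#'   `contrast` (`"tolerant"` or `"sensitive"`), `fc` (signed, `|fc| >= 1`;
#'   positive plants up-regulation of the stressed library, negative
#'   down-regulation).
#' @param base_expression Median tpm of the log-normal abundance profile.
#' @param abundance_sdlog Log-sd of the abundance profile.
#' @param dispersion Gamma-Poisson overdispersion (extra squared CV of
#'   expression between resampled libraries); 0 gives pure multinomial
#'   sampling. The default (0.002, about 4.5 percent extra CV) models
#'   technical, resampling-level reproducibility -- the regime the
#'   Audic-Claverie test assumes; it is exposed for sensitivity analyses
#'   because the between-genotype variance within a bulk is not known.
#' @param singleton_fraction Fraction of unitags forced to count exactly 1
#'   per library so singleton exclusion is always exercised; drawn only
#'   from naturally rare unitags (expected count below 2) and never from
#'   planted-effect unitags, so the forcing does not fabricate
#'   differential expression.
#' @param sister_fraction Fraction of aquaporin unitags that also emit a
#'   sister-tag (single-base substitution variant anchoring the same EST).
#' @param est_length Min/max EST sequence length.
#' @param seed Integer seed; a fixed seed makes every generated artifact
#'   byte-identical across runs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_background_ests = 18000,
                       n_aquaporin_isoforms = 42,
                       unitag_weights = stats::dgeom(0:29, 0.30),
                       library_sizes = c(SD24T = 2e5, SDTC = 2e5,
                                         SD24S = 2e5, SDSC = 2e5),
                       planted_effects = NULL,
                       base_expression = 30,
                       abundance_sdlog = 1.3,
                       dispersion = 0.002,
                       singleton_fraction = 0.05,
                       sister_fraction = 0,
                       est_length = c(200, 600),
                       seed = 1L) {
  if (length(library_sizes) != 4L || any(library_sizes <= 0) ||
      any(library_sizes != round(library_sizes)))
    stop("library_sizes must be four positive integers")
  if (is.null(names(library_sizes))) names(library_sizes) <- LIBRARY_META$id
  if (!setequal(names(library_sizes), LIBRARY_META$id))
    stop("library_sizes must be named SD24T, SDTC, SD24S, SDSC")
  if (!is.null(planted_effects)) {
    stopifnot(is.data.frame(planted_effects),
              all(c("unitag", "contrast", "fc") %in%
                    names(planted_effects)))
    if (any(planted_effects$fc == 0))
      stop("planted fold changes must be non-zero")
    if (any(abs(planted_effects$fc) < 1))
      stop("planted fold changes are signed: |fc| must be >= 1")
    if (!all(planted_effects$contrast %in% c("tolerant", "sensitive")))
      stop("planted effect contrast must be 'tolerant' or 'sensitive'")
  }
  if (length(unitag_weights) < 1L || length(unitag_weights) > 30L ||
      any(unitag_weights < 0) || sum(unitag_weights) <= 0)
    stop("unitag_weights must be non-negative weights over 1..30")
  stopifnot(n_background_ests >= 0, n_aquaporin_isoforms >= 0,
            base_expression > 0, abundance_sdlog >= 0, dispersion >= 0,
            singleton_fraction >= 0, singleton_fraction < 1,
            sister_fraction >= 0, sister_fraction <= 1,
            length(est_length) == 2L)
  if (est_length[1] < TAG_LENGTH + 4L)
    stop("EST length cannot host a full 26-bp tag site")
  structure(list(
    n_background_ests = as.integer(n_background_ests),
    n_aquaporin_isoforms = as.integer(n_aquaporin_isoforms),
    unitag_weights = unitag_weights,
    library_sizes = library_sizes[LIBRARY_META$id],
    planted_effects = planted_effects,
    base_expression = base_expression,
    abundance_sdlog = abundance_sdlog,
    dispersion = dispersion,
    singleton_fraction = singleton_fraction,
    sister_fraction = sister_fraction,
    est_length = est_length,
    seed = as.integer(seed)), class = "sim_config")
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# random sequence guaranteed to carry >= 1 extractable 26-bp tag site
.random_est_sequence <- function(len) {
  s <- .random_dna(len)
  pos <- sample.int(len - TAG_LENGTH + 1L, 1L)
  paste0(substr(s, 1L, pos - 1L), TAG_ANCHOR,
         substr(s, pos + 4L, len))
}

BACKGROUND_ANNOTATIONS <- c(
  "heat shock protein 70", "actin depolymerizing factor",
  "ribosomal protein L7", "sucrose synthase", "catalase isozyme A",
  "glyceraldehyde-3-phosphate dehydrogenase", "histone H2B",
  "pipecolate oxidase", "serine/threonine kinase",
  "late embryogenesis abundant protein", "cellulose synthase",
  "ubiquitin-conjugating enzyme", "ferredoxin-NADP reductase",
  "zinc finger transcription factor", "cytochrome P450 monooxygenase",
  "unknown protein", "hypothetical protein", "unnamed protein product")

BACKGROUND_GO <- c(
  "protein binding;metabolic process", "translation;ribosome",
  "oxidation-reduction process", "response to heat",
  "carbohydrate metabolic process", "DNA binding;nucleus", "")

#' Generate a synthetic EST reference collection
#'
#' Produces background records and aquaporin records whose annotations have
#' the form `"<species prefix> aquaporin <SUBFAMILY><group>-<member>"`
#' (some additionally carry the GO term `"water transport"`). Every
#' sequence carries at least one CATG site with >= 22 nt downstream, so a
#' full 26-bp tag is always extractable, and every record's canonical tag
#' is unique across the collection. Source databases are drawn from a
#' ranked list with the sugarcane databanks first.
#'
#' @param config A [sim_config].
#' @return An `est_reference` with one row per EST.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  labels <- character(0)
  subfam_groups <- list(PIP = 1:2, TIP = 1:5, NIP = 1:3, SIP = 1:2)
  while (length(labels) < config$n_aquaporin_isoforms) {
    sf <- sample(SUBFAMILIES, 1L, prob = c(0.45, 0.30, 0.15, 0.10))
    lab <- sprintf("%s%d-%d", sf, sample(subfam_groups[[sf]], 1L),
                   sample.int(8L, 1L))
    if (!lab %in% labels) labels <- c(labels, lab)
  }
  n_per_iso <- if (length(labels))
    sample(seq_along(config$unitag_weights), length(labels),
           replace = TRUE, prob = config$unitag_weights) else integer()
  iso_of_est <- rep(labels, n_per_iso)
  n_aq <- length(iso_of_est)
  n_bg <- config$n_background_ests
  n <- n_aq + n_bg
  db_idx <- sample.int(nrow(DB_SPECIES), n, replace = TRUE,
                       prob = DB_SPECIES$weight)
  database <- DB_SPECIES$database[db_idx]
  species <- DB_SPECIES$species[db_idx]
  prefix <- DB_SPECIES$prefix[db_idx]
  long_name <- c(PIP = "plasma membrane intrinsic protein",
                 TIP = "tonoplast intrinsic protein",
                 NIP = "nodulin-26-like intrinsic protein",
                 SIP = "small basic intrinsic protein")
  annotation <- character(n)
  go_terms <- character(n)
  if (n_aq) {
    # three annotation styles: the plain family keyword form, the long
    # subfamily name, and (as in real dbEST records) an uninformative
    # description identifiable only through its GO term
    style <- stats::runif(n_aq)
    sf <- substr(iso_of_est, 1L, 3L)
    annotation[seq_len(n_aq)] <- ifelse(
      style < 0.70,
      paste(prefix[seq_len(n_aq)], "aquaporin", iso_of_est),
      ifelse(style < 0.85,
             paste(prefix[seq_len(n_aq)], long_name[sf], iso_of_est),
             "unknown protein"))
    go_terms[seq_len(n_aq)] <- ifelse(
      style >= 0.85 | stats::runif(n_aq) < 0.5,
      "water transport;transport", "transport")
  }
  if (n_bg) {
    annotation[n_aq + seq_len(n_bg)] <-
      sample(BACKGROUND_ANNOTATIONS, n_bg, replace = TRUE)
    go_terms[n_aq + seq_len(n_bg)] <-
      sample(BACKGROUND_GO, n_bg, replace = TRUE)
  }
  lens <- sample(config$est_length[1]:config$est_length[2], n,
                 replace = TRUE)
  sequence <- vapply(lens, .random_est_sequence, character(1))
  # canonical tags must be unique so each unitag has one provenance entry
  repeat {
    tags <- extract_tag(sequence)
    dup <- which(duplicated(tags))
    if (!length(dup)) break
    sequence[dup] <- vapply(lens[dup], .random_est_sequence, character(1))
  }
  ref <- est_reference(sprintf("SYN%05d", seq_len(n)), database, species,
                       annotation, go_terms, sequence)
  ref$isoform <- c(iso_of_est, rep(NA_character_, n_bg))
  ref
}

.canonical_offsets <- function(sequences) {
  vapply(sequences, function(s) {
    hits <- gregexpr(TAG_ANCHOR, s, fixed = TRUE)[[1]]
    hits <- hits[hits != -1L & hits + TAG_LENGTH - 1L <= nchar(s)]
    as.integer(hits[length(hits)] - 1L)       # 0-based
  }, integer(1), USE.NAMES = FALSE)
}

.mutate_base <- function(tag, pos) {
  other <- setdiff(c("A", "C", "G", "T"), substr(tag, pos, pos))
  substr(tag, pos, pos) <- sample(other, 1L)
  tag
}

#' Base expression profile of the unitag universe
#'
#' Deterministically (given the config seed) assigns every canonical unitag
#' of the reference a relative abundance from a log-normal profile, plus
#' provenance (EST, 0-based offset) and the isoform identity parsed from
#' the EST annotation. Sister-tags, when enabled, are added as distinct
#' unitags anchoring the same EST at the same offset with a fraction of the
#' parent abundance.
#'
#' @param config A [sim_config].
#' @param reference Output of [generate_reference()].
#' @return Data frame (the ground-truth skeleton): `unitag`, `est`,
#'   `offset`, `isoform`, `subfamily`, `sister`, `base_weight`.
#' @export
expression_profile <- function(config, reference) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tags <- extract_tag(reference$sequence)
  offs <- .canonical_offsets(reference$sequence)
  # generator references carry their true isoform; user-supplied ones are
  # parsed from the annotation text
  iso <- if ("isoform" %in% names(reference)) reference$isoform
  else vapply(reference$annotation, function(a) {
    p <- parse_isoform(a)
    if (is.null(p)) NA_character_ else p$label
  }, character(1), USE.NAMES = FALSE)
  truth <- data.frame(unitag = tags, est = reference$id, offset = offs,
                      isoform = iso,
                      subfamily = ifelse(is.na(iso), NA_character_,
                                         substr(iso, 1L, 3L)),
                      sister = FALSE, stringsAsFactors = FALSE)
  if (config$sister_fraction > 0) {
    aq <- which(!is.na(truth$isoform))
    k <- floor(config$sister_fraction * length(aq))
    if (k > 0) {
      pick <- aq[sample.int(length(aq), k)]
      sis <- truth[pick, , drop = FALSE]
      for (i in seq_len(nrow(sis))) {
        repeat {
          cand <- .mutate_base(sis$unitag[i],
                               sample(5:TAG_LENGTH, 1L))
          if (!cand %in% truth$unitag && !cand %in% sis$unitag) break
        }
        sis$unitag[i] <- cand
      }
      sis$sister <- TRUE
      truth <- rbind(truth, sis)
    }
  }
  truth$base_weight <- stats::rlnorm(nrow(truth),
                                     log(config$base_expression),
                                     config$abundance_sdlog)
  truth$base_weight[truth$sister] <-
    0.3 * truth$base_weight[truth$sister]
  rownames(truth) <- NULL
  truth
}

#' Generate the four bulked tag libraries plus ground truth
#'
#' Counts follow a gamma-mixed Poisson (negative binomial) model
#' conditioned to the exact configured library totals by multinomial
#' allocation: per library, expected tpm are perturbed by i.i.d. gamma
#' weights of mean 1 and squared CV `dispersion`, then the library total is
#' allocated multinomially over the perturbed expectations. Planted effects
#' multiply the expected tpm of the stressed library of their contrast
#' (positive fc up, negative fc down by `1/|fc|`). A configured fraction of
#' unitags (never planted-effect ones) is forced to count exactly 1 per
#' library so downstream singleton exclusion is always exercised.
#'
#' @param config A [sim_config].
#' @param reference Output of [generate_reference()].
#' @param effects Planted-effect data frame overriding
#'   `config$planted_effects` (columns `unitag`, `contrast`, `fc`).
#'   Referencing an unknown unitag is an error.
#' @param replicate Integer replicate index: varies only the count draws,
#'   keeping reference and expression profile fixed (for replicate
#'   simulations).
#' @return List with `libraries` (named list of four [tag_library]) and
#'   `truth` (the [expression_profile()] table extended with per-library
#'   expected tpm `exp_tpm_*`, per-contrast true status
#'   `status_tolerant` / `status_sensitive`, and per-library forced
#'   singleton flags `single_*`).
#' @export
generate_libraries <- function(config, reference,
                               effects = config$planted_effects,
                               replicate = 1L) {
  stopifnot(inherits(config, "sim_config"))
  truth <- expression_profile(config, reference)
  n <- nrow(truth)
  mult <- matrix(1, n, 4L, dimnames = list(NULL, LIBRARY_META$id))
  truth$status_tolerant <- "ns"
  truth$status_sensitive <- "ns"
  effect_idx <- integer(0)
  if (!is.null(effects) && nrow(effects)) {
    miss <- setdiff(effects$unitag, truth$unitag)
    if (length(miss))
      stop(sprintf("planted effect on unknown unitag(s): %s",
                   paste(utils::head(miss, 3L), collapse = ", ")))
    for (i in seq_len(nrow(effects))) {
      j <- match(effects$unitag[i], truth$unitag)
      lib <- if (effects$contrast[i] == "tolerant") "SD24T" else "SD24S"
      fc <- effects$fc[i]
      mult[j, lib] <- mult[j, lib] * (if (fc > 0) fc else 1 / abs(fc))
      col <- paste0("status_", effects$contrast[i])
      truth[[col]][j] <- if (fc > 0) "UR" else "DR"
      effect_idx <- c(effect_idx, j)
    }
  }
  libs <- vector("list", 4L)
  names(libs) <- LIBRARY_META$id
  for (j in seq_len(4L)) {
    id <- LIBRARY_META$id[j]
    N <- config$library_sizes[[id]]
    mu <- truth$base_weight * mult[, j]
    exp_tpm <- 1e6 * mu / sum(mu)
    truth[[paste0("exp_tpm_", id)]] <- exp_tpm
    set.seed(config$seed + 10L + j + 101L * (as.integer(replicate) - 1L))
    w <- if (config$dispersion > 0)
      mu * stats::rgamma(n, shape = 1 / config$dispersion,
                         rate = 1 / config$dispersion)
    else mu
    k <- floor(config$singleton_fraction * n)
    counts <- integer(n)
    singles <- integer(0)
    if (k > 0) {
      # only naturally rare unitags (expected count < 2) are forced to
      # count 1: forcing abundant ones would fabricate differential
      # expression between the paired libraries
      candidates <- setdiff(which(exp_tpm * N / 1e6 < 2), effect_idx)
      singles <- candidates[sample.int(length(candidates),
                                       min(k, length(candidates)))]
      counts[singles] <- 1L
    }
    rest <- setdiff(seq_len(n), singles)
    counts[rest] <- as.integer(
      stats::rmultinom(1L, N - length(singles), prob = w[rest]))
    truth[[paste0("single_", id)]] <- seq_len(n) %in% singles
    keep <- counts > 0L
    libs[[j]] <- tag_library(id, LIBRARY_META$bulk[j],
                             LIBRARY_META$treatment[j],
                             stats::setNames(counts[keep],
                                             truth$unitag[keep]),
                             N = N)
  }
  list(libraries = libs, truth = truth)
}

#' Read / write the ground-truth table
#'
#' Full-precision TSV serialisation of the truth table so it round-trips
#' losslessly.
#'
#' @param truth Truth data frame from [generate_libraries()].
#' @param path File path.
#' @return `read_truth` returns the data frame; `write_truth` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  df
}
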