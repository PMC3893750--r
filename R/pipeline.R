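#' Pipeline configuration
#'
#' Validates the full run configuration up front, before any computation:
#' either a [sim_config] (the four libraries and the reference are then
#' simulated) or concrete `libraries` + `reference`, plus the contrasts and
#' the annotation parameters.
#'
#' @param sim Optional [sim_config]; when given, `libraries` and
#'   `reference` are generated.
#' @param libraries Named list of [tag_library] (ignored when `sim` is
#'   given).
#' @param reference An `est_reference` (ignored when `sim` is given).
#' @param contrasts List of [contrast_spec]; defaults to the two bulk
#'   contrasts SD24T vs SDTC ("tolerant") and SD24S vs SDSC ("sensitive").
#' @param alpha Significance level of the UR/DR calls.
#' @param keywords Family-mining annotation keywords.
#' @param go_phrase Family-mining GO phrase.
#' @param db_priority Database ranking for [best_hit()].
#' @param mode Anchoring mode, `"exact-prefix"` or `"one-mismatch"`.
#' @param top_n Row count of the top-expressed table.
#' @param out_dir Output directory for the report TSVs and manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, libraries = NULL, reference = NULL,
                            contrasts = NULL, alpha = 0.05,
                            keywords = default_family_keywords(),
                            go_phrase = "water transport",
                            db_priority = default_db_priority(),
                            mode = c("exact-prefix", "one-mismatch"),
                            top_n = 30, out_dir = tempfile("sagetag_run")) {
  mode <- match.arg(mode)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (is.null(contrasts))
    contrasts <- list(
      tolerant = contrast_spec("tolerant", "SD24T", "SDTC", alpha),
      sensitive = contrast_spec("sensitive", "SD24S", "SDSC", alpha))
  lib_ids <- if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    names(sim$library_sizes)
  } else {
    if (is.null(libraries) || is.null(reference))
      stop("either 'sim' or both 'libraries' and 'reference' are required")
    if (is.null(names(libraries)))
      names(libraries) <- vapply(libraries, `[[`, character(1), "id")
    names(libraries)
  }
  for (cs in contrasts) {
    stopifnot(inherits(cs, "contrast_spec"))
    unknown <- setdiff(c(cs$numerator, cs$denominator), lib_ids)
    if (length(unknown))
      stop(sprintf("contrast '%s' references unknown library id '%s'",
                   cs$name, unknown[1]))
  }
  structure(list(sim = sim, libraries = libraries, reference = reference,
                 contrasts = contrasts, alpha = alpha,
                 keywords = keywords, go_phrase = go_phrase,
                 db_priority = db_priority, mode = mode,
                 top_n = top_n, out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # configuration digest for the run manifest: stable across identical runs
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keep <- config[setdiff(names(config), "out_dir")]
  writeLines(utils::capture.output(utils::str(keep, digits.d = 17,
                                              vec.len = 1e6)), tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the whole tag-profiling pipeline
#'
#' Executes: (optional) simulation, singleton exclusion, tpm
#' normalisation, the configured exact-test contrasts, unitag-to-EST
#' anchoring with best-hit selection, family mining and isoform parsing,
#' and all report tables; writes every artifact plus a reproducibility
#' manifest (configuration hash, seed, versions) under `config$out_dir`.
#' Record counts in and out of every filter are logged per stage.
#'
#' @param config A [pipeline_config].
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with `libraries`, `truth` (when simulated),
#'   `results` (per-contrast data frames), `hits`, `best`, `isoform_map`,
#'   `reports` (named list of tables) and `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(config$sim)) {
    stage_log(quiet, "simulate: generating reference and libraries (seed %d)",
              config$sim$seed)
    reference <- generate_reference(config$sim)
    gen <- generate_libraries(config$sim, reference)
    libraries <- gen$libraries
    truth <- gen$truth
    write_reference(reference, file.path(config$out_dir, "reference.fasta"),
                    file.path(config$out_dir, "reference_annotations.tsv"))
    write_truth(truth, file.path(config$out_dir, "ground_truth.tsv"))
  } else {
    reference <- config$reference
    libraries <- config$libraries
  }

  for (nm in names(libraries)) {
    before <- length(libraries[[nm]]$counts)
    libraries[[nm]] <- exclude_singletons(libraries[[nm]])
    stage_log(quiet, "singletons [%s]: %d unitags in, %d removed, %d kept",
              nm, before, before - length(libraries[[nm]]$counts),
              length(libraries[[nm]]$counts))
    write_library(libraries[[nm]],
                  file.path(config$out_dir, paste0(nm, "_counts.tsv")))
  }
  tpms <- tpm_table(libraries)

  results <- lapply(config$contrasts, run_contrast, libraries = libraries)
  names(results) <- vapply(config$contrasts, `[[`, character(1), "name")
  for (cn in names(results)) {
    stage_log(quiet, "contrast [%s]: %d unitags, %d UR, %d DR", cn,
              nrow(results[[cn]]), sum(results[[cn]]$call == "UR"),
              sum(results[[cn]]$call == "DR"))
    write_report(results[[cn]],
                 file.path(config$out_dir,
                           paste0("contrast_", gsub("\\W+", "_", cn),
                                  ".tsv")))
  }

  mined <- mine_family(reference, config$keywords, config$go_phrase)
  family_ref <- reference[mined$matched, , drop = FALSE]
  stage_log(quiet, "mine_family: %d of %d ESTs matched (%d via GO only)",
            nrow(family_ref), nrow(reference),
            sum(mined$source == "go", na.rm = TRUE))

  observed <- sort(unique(unlist(lapply(libraries,
                                        function(l) names(l$counts)))))
  hits <- anchor_all(observed, family_ref, mode = config$mode)
  stage_log(quiet, "anchor [%s]: %d observed unitags, %d hits, %d anchored",
            config$mode, length(observed), nrow(hits),
            length(unique(hits$unitag)))
  best <- do.call(rbind, c(lapply(
    split(hits, hits$unitag), best_hit, reference = reference,
    db_priority = config$db_priority), list(empty_hits())))
  rownames(best) <- NULL

  key <- paste(reference$database, reference$id)
  ann <- reference$annotation[match(paste(best$database, best$est), key)]
  iso <- vapply(seq_along(ann), function(i) {
    p <- parse_isoform(ann[i])
    if (is.null(p)) NA_character_ else p$label
  }, character(1))
  isoform_map <- data.frame(unitag = best$unitag, isoform = iso,
                            annotation = ann, stringsAsFactors = FALSE)
  write_report(cbind(best, annotation = ann, isoform = iso),
               file.path(config$out_dir, "best_hits.tsv"))

  reports <- list()
  reports$isoform_table <- isoform_table(results, isoform_map)
  reports$top_expressed <- top_expressed(
    tpms, n = config$top_n, unitags = isoform_map$unitag,
    annotations = isoform_map)
  if (all(c("tolerant", "sensitive") %in% names(results))) {
    # the two bulk contrasts observe different unitag universes; the
    # divergence table is defined on their intersection
    reports$divergence <- suppressWarnings(divergence_table(
      results$tolerant, results$sensitive,
      annotations = isoform_map))
    stage_log(quiet,
              "divergence: %d unitags in the universe intersection, %d rows",
              length(intersect(results$tolerant$unitag,
                               results$sensitive$unitag)),
              nrow(reports$divergence))
    reports$markers <- candidate_markers(
      reports$isoform_table, "tolerant", "sensitive",
      divergence = reports$divergence, isoform_map = isoform_map)
  }
  reports$fc_matrix <- fc_matrix(results, isoform_map)
  write_report(reports$isoform_table,
               file.path(config$out_dir, "isoform_table.tsv"))
  write_report(reports$top_expressed,
               file.path(config$out_dir, "top_expressed.tsv"), digits = 0)
  if (!is.null(reports$divergence))
    write_report(reports$divergence,
                 file.path(config$out_dir, "divergence.tsv"))
  if (!is.null(reports$markers))
    write_report(reports$markers,
                 file.path(config$out_dir, "candidate_markers.tsv"))
  write_report(reports$fc_matrix,
               file.path(config$out_dir, "fc_matrix.tsv"))

  manifest <- data.frame(
    key = c("package_version", "r_version", "config_md5", "seed", "alpha",
            "mode", "n_libraries", "n_contrasts"),
    value = c(as.character(utils::packageVersion("sagetag")),
              paste(R.version$major, R.version$minor, sep = "."),
              config_hash(config),
              if (is.null(config$sim)) NA else config$sim$seed,
              config$alpha, config$mode, length(libraries),
              length(results)),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log(quiet, "done: outputs in %s", config$out_dir)

  invisible(list(libraries = libraries, truth = truth, tpms = tpms,
                 results = results, hits = hits, best = best,
                 isoform_map = isoform_map, reports = reports,
                 manifest = manifest))
}
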