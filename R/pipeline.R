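# End-to-end orchestration: validated run configuration, staged execution
# with stable output filenames, a run manifest, and a human-readable report.

.RUN_CONFIG_KEYS <- c(
  "library", "counts", "sample_sheet", "output_dir",
  "pseudocount", "control_categories", "min_anchor_partners",
  "z_cut", "lethality_cut", "positivity_cut", "sd_tol",
  "top_k", "seed", "verbosity"
)

#' Build a validated run configuration
#'
#' Named parameters for \code{\link{runPipeline}}; unknown keys are
#' rejected (typo safety) and the configuration serializes verbatim into
#' the run manifest.
#'
#' @param library path to the guide library TSV.
#' @param counts path to the construct count TSV.
#' @param sample_sheet path to the sample sheet TSV.
#' @param output_dir directory for all outputs (created if needed).
#' @param pseudocount RPM pseudocount.
#' @param control_categories negative-control guide categories.
#' @param min_anchor_partners minimum partners per anchor fit.
#' @param z_cut synergy threshold on the gene-pair z-score.
#' @param lethality_cut numeric LFC cut, or \code{"screen_average"}.
#' @param positivity_cut single-KO LFC cut for compensation calls.
#' @param sd_tol degenerate-variance guard.
#' @param top_k hits listed in the report.
#' @param seed optional seed recorded in the manifest (simulation only; the
#'   scoring pipeline itself is deterministic).
#' @param verbosity 0 (quiet) or 1.
#' @param ... rejected; catches misspelled keys.
#' @return A named list with class \code{"run_config"}.
#' @export
runConfig <- function(library, counts, sample_sheet, output_dir,
                      pseudocount = 1, control_categories = "non_targeting",
                      min_anchor_partners = 10, z_cut = -4,
                      lethality_cut = "screen_average", positivity_cut = 0.5,
                      sd_tol = 1e-8, top_k = 5L, seed = NULL, verbosity = 1L,
                      ...) {
  extra <- list(...)
  if (length(extra)) {
    csStop("config_error", "unknown configuration key(s): %s",
           paste(names(extra), collapse = ", "))
  }
  if (!is.numeric(lethality_cut) && !identical(lethality_cut, "screen_average")) {
    csStop("config_error", "lethality_cut must be numeric or \"screen_average\"")
  }
  structure(list(
    library = library, counts = counts, sample_sheet = sample_sheet,
    output_dir = output_dir, pseudocount = pseudocount,
    control_categories = control_categories,
    min_anchor_partners = min_anchor_partners, z_cut = z_cut,
    lethality_cut = lethality_cut, positivity_cut = positivity_cut,
    sd_tol = sd_tol, top_k = as.integer(top_k), seed = seed,
    verbosity = as.integer(verbosity)
  ), class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} needs the yaml
#'   package; \code{.json} uses jsonlite).
#' @param ... overrides applied on top of the file's values.
#' @return A \code{run_config} (see \code{\link{runConfig}}).
#' @export
readRunConfig <- function(path, ...) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      csStop("config_error", "reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  bad <- setdiff(names(vals), .RUN_CONFIG_KEYS)
  if (length(bad)) {
    csStop("config_error", "unknown configuration key(s): %s", paste(bad, collapse = ", "))
  }
  do.call(runConfig, vals)
}

.stageMsg <- function(config, fmt, ...) {
  if (config$verbosity > 0L) message(sprintf(fmt, ...))
}

#' Run the full screen-analysis pipeline
#'
#' Reads the guide library, counts and sample sheet, computes LFCs, base
#' LFCs, anchor fits, gene-pair interaction scores, hit calls and QC, and
#' writes every artifact with stable filenames plus a manifest recording
#' the configuration, input checksums and package version. On a stage
#' failure, outputs written so far are renamed with a \code{.partial}
#' suffix and the error names the stage.
#'
#' @param config a \code{run_config} from \code{\link{runConfig}}.
#' @return The artifact bundle (list of tables and paths), invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(writer, obj, name, ...) {
    path <- file.path(config$output_dir, name)
    writer(obj, path, ...)
    written <<- c(written, path)
    path
  }
  on_fail <- function(stage_name, e) {
    for (p in written) {
      if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
    }
    csStop("pipeline_error", "stage '%s' failed: %s", stage_name, conditionMessage(e))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_fail(name, e))
  }

  lib <- stage("read_library", readGuideLibrary(config$library))
  catalog <- stage("build_catalog", buildAllByAllCatalog(lib))
  counts <- stage("read_counts", readCounts(config$counts, catalog, config$sample_sheet))
  .stageMsg(config, "loaded %d guides, %d constructs, %d samples",
            length(lib), length(catalog), ncol(counts))

  lfc_rep <- stage("lfc", computeLfc(countsToLog2RPM(counts, config$pseudocount)))
  lfc <- stage("average_replicates", averageReplicates(lfc_rep))
  emit(writeLfc, lfc_rep, "lfc_replicates.tsv")
  emit(writeLfc, lfc, "lfc.tsv")

  base <- stage("base_lfc", computeBaseLfc(lfc, config$control_categories))
  emit(.writeTsv, base, "base_lfc.tsv")
  fits <- stage("anchor_fit",
                fitAnchorModels(lfc, base, config$min_anchor_partners, config$sd_tol))
  emit(.writeTsv, fits$fits, "anchor_fits.tsv")
  scores <- stage("gene_pairs", computeFdr(scoreGenePairs(fits)))
  emit(writeGenePairScores, scores, "gene_pair_scores.tsv")

  single_ko <- stage("single_ko", singleKoLfc(lfc, config$control_categories))
  emit(.writeTsv, single_ko, "single_ko_lfc.tsv")
  lethality_cut <- if (identical(config$lethality_cut, "screen_average")) NULL else config$lethality_cut
  hits <- stage("hit_calling",
                classifyPairs(scores, single_ko, z_cut = config$z_cut,
                              lethality_cut = lethality_cut,
                              positivity_cut = config$positivity_cut))
  emit(writeHitCalls, hits, "hit_calls.tsv")

  qc <- stage("qc", qcReport(lfc_rep, base, lib, fits$excluded))
  emit(writeQcReport, qc, "qc_report.json")

  manifest <- list(
    package = "comboscreen",
    version = as.character(utils::packageVersion("comboscreen")),
    config = unclass(config),
    inputs = lapply(stats::setNames(
      c(config$library, config$counts, config$sample_sheet),
      c("library", "counts", "sample_sheet")
    ), function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = basename(written)
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  written <- c(written, manifest_path)

  bundle <- list(
    library = lib, catalog = catalog, counts = counts,
    lfc_replicates = lfc_rep, lfc = lfc, base = base,
    anchor_fits = fits, scores = scores, single_ko = single_ko,
    hits = hits, qc = qc, manifest = manifest, config = config,
    output_dir = config$output_dir, files = written
  )
  report <- writeReport(bundle, file.path(config$output_dir, "report.md"))
  bundle$report <- report
  .stageMsg(config, "pipeline complete: %d gene pairs scored, %d synergistic_lethal",
            nrow(scores), sum(hits$label == "synergistic_lethal"))
  invisible(bundle)
}

#' Write a human-readable run summary
#'
#' Markdown summary of library composition, construct classes, screen
#' averages, hit counts by label, the top-k synergistic-lethal table and
#' QC correlations. Regeneration from the same bundle is idempotent.
#'
#' @param bundle pipeline bundle from \code{\link{runPipeline}}.
#' @param path optional output path.
#' @return The report text (character vector of lines), invisibly if
#'   written to a file.
#' @export
writeReport <- function(bundle, path = NULL) {
  pc <- pairClassCounts(bundle$catalog)
  avg <- screenAverageLfc(bundle$scores)
  lab_tab <- table(factor(bundle$hits$label, levels = .HIT_LABELS))
  top <- rankTopHits(bundle$hits, bundle$config$top_k %||% 5L)
  lines <- c(
    "# Combinatorial screen report",
    "",
    sprintf("- guides: %d (%d SpCas9, %d SaCas9)", length(bundle$library),
            sum(guides(bundle$library)$ortholog == "SpCas9"),
            sum(guides(bundle$library)$ortholog == "SaCas9")),
    sprintf("- constructs: %d (%s)", length(bundle$catalog),
            paste(sprintf("%s %d", names(pc), pc), collapse = ", ")),
    sprintf("- screen-average gene-pair LFC: %s",
            paste(sprintf("%s %.4g", names(avg), avg), collapse = ", ")),
    sprintf("- gene pairs scored: %d", sum(!bundle$scores$same_gene)),
    "",
    "## Hit counts",
    sprintf("- %s: %d", names(lab_tab), as.integer(lab_tab)),
    "",
    sprintf("## Top %d synergistic lethal hits", bundle$config$top_k %||% 5L)
  )
  if (nrow(top)) {
    lines <- c(lines,
      "",
      "| condition | gene_i | gene_j | z_gene | mean_lfc | fdr_q |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %.4g | %.4g | %.3g |",
              top$condition, top$gene_i, top$gene_j, top$z_gene,
              top$mean_observed_lfc, top$fdr_q))
  } else {
    lines <- c(lines, "", "(none)")
  }
  qc <- bundle$qc
  lines <- c(lines, "", "## QC")
  if (!is.null(qc$replicate_correlation)) {
    r <- qc$replicate_correlation
    lines <- c(lines, sprintf("- replicate Pearson r (%s rep%s vs rep%s): %.4g",
                              r$condition, r$replicate_a, r$replicate_b, r$pearson_r))
  }
  o <- qc$ortholog_concordance
  lines <- c(lines, sprintf("- ortholog concordance (%s): r = %.4g over %d genes",
                            o$condition, o$pearson_r, o$n_genes))
  lines <- c(lines, sprintf("- excluded anchors: %d", qc$n_excluded_anchors))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
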