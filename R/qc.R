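# Screen quality control: replicate concordance, Cas9-ortholog concordance
# and essential/non-targeting control separation.

#' Replicate LFC concordance
#'
#' Pearson correlation of construct LFCs between every pair of replicates
#' within each condition, over the constructs finite in both. A
#' well-behaved screen shows replicate r in the 0.9+ range.
#'
#' @param lfc a replicate-level \code{SummarizedExperiment} with assay
#'   \code{"lfc"} (not replicate-averaged).
#' @return data.frame(condition, replicate_a, replicate_b, n_shared,
#'   pearson_r); r is NA (flagged) when fewer than 3 constructs are shared.
#' @export
replicateCorrelation <- function(lfc) {
  cd <- SummarizedExperiment::colData(lfc)
  if (!"replicate" %in% names(cd)) cd$replicate <- rownames(cd)
  m <- SummarizedExperiment::assay(lfc, "lfc")
  out <- list()
  for (cc in unique(as.character(cd$condition))) {
    cols <- which(cd$condition == cc)
    if (length(cols) < 2L) next
    for (a in seq_along(cols)[-length(cols)]) {
      for (b in seq((a + 1L), length(cols))) {
        va <- m[, cols[a]]; vb <- m[, cols[b]]
        ok <- is.finite(va) & is.finite(vb)
        r <- if (sum(ok) >= 3L) stats::cor(va[ok], vb[ok]) else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          condition = cc,
          replicate_a = as.character(cd$replicate[cols[a]]),
          replicate_b = as.character(cd$replicate[cols[b]]),
          n_shared = sum(ok), pearson_r = r,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    csStop("config_error", "replicate correlation needs >= 2 replicates in some condition")
  }
  res <- do.call(rbind, out)
  if (anyNA(res$pearson_r)) csWarn("replicate pair(s) with < 3 shared constructs flagged NA")
  res
}

#' Cas9-ortholog concordance of single-knockout effects
#'
#' Per gene, the mean base LFC of its SpCas9 guides versus its SaCas9
#' guides; Pearson correlation over genes targeted by both orthologs.
#'
#' @param base base LFC table from \code{\link{computeBaseLfc}}.
#' @param library the \linkS4class{GuideLibrary} (maps guides to genes).
#' @return data.frame(condition, n_genes, pearson_r); r is NA (flagged) when
#'   fewer than 3 genes are covered by both orthologs.
#' @export
orthologConcordance <- function(base, library) {
  g <- guides(library)
  g <- g[g$category == "targeting", , drop = FALSE]
  b <- base[base$guide_id %in% g$guide_id, , drop = FALSE]
  b$gene <- g$target_gene[match(b$guide_id, g$guide_id)]
  out <- lapply(split(b, b$condition), function(d) {
    key <- paste(d$gene, d$ortholog, sep = "\r")
    mu <- .groupSum(d$base_lfc, key) / .groupSum(rep(1, nrow(d)), key)
    parts <- do.call(rbind, strsplit(names(mu), "\r", fixed = TRUE))
    sp <- mu[parts[, 2L] == "SpCas9"]; names(sp) <- parts[parts[, 2L] == "SpCas9", 1L]
    sa <- mu[parts[, 2L] == "SaCas9"]; names(sa) <- parts[parts[, 2L] == "SaCas9", 1L]
    shared <- intersect(names(sp), names(sa))
    data.frame(
      condition = d$condition[1L], n_genes = length(shared),
      pearson_r = if (length(shared) >= 3L) stats::cor(sp[shared], sa[shared]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (anyNA(res$pearson_r)) csWarn("ortholog concordance undefined (< 3 genes with both orthologs)")
  res
}

#' Control separation of single-knockout effects
#'
#' Medians of the per-guide base LFC by guide category, and a standardized
#' dropout statistic: (median non-targeting - median essential-control)
#' divided by the pooled MAD of the two groups (root mean square of the two
#' MADs). Larger values mean essential controls drop out more cleanly.
#'
#' @param base base LFC table from \code{\link{computeBaseLfc}}.
#' @param library the \linkS4class{GuideLibrary}.
#' @return data.frame(condition, median_targeting, median_non_targeting,
#'   median_essential, separation).
#' @export
controlSeparation <- function(base, library) {
  g <- guides(library)
  b <- base
  b$category <- g$category[match(b$guide_id, g$guide_id)]
  out <- lapply(split(b, b$condition), function(d) {
    nt <- d$base_lfc[d$category == "non_targeting"]
    ess <- d$base_lfc[d$category == "essential_control"]
    if (!length(nt) || !length(ess)) {
      csStop("config_error", "control separation needs both non-targeting and essential-control guides")
    }
    pooled <- sqrt((stats::mad(nt)^2 + stats::mad(ess)^2) / 2)
    num <- stats::median(nt) - stats::median(ess)
    sep <- if (pooled > 1e-12) num / pooled else if (abs(num) < 1e-12) 0 else sign(num) * Inf
    data.frame(
      condition = d$condition[1L],
      median_targeting = stats::median(d$base_lfc[d$category == "targeting"]),
      median_non_targeting = stats::median(nt),
      median_essential = stats::median(ess),
      separation = sep,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble a QC report
#'
#' @param lfc replicate-level LFC \code{SummarizedExperiment}.
#' @param base base LFC table (replicate-averaged scoring input).
#' @param library the \linkS4class{GuideLibrary}.
#' @param excluded optional anchor-exclusion table from
#'   \code{\link{fitAnchorModels}}.
#' @return A list of QC tables with class \code{"qc_report"}.
#' @export
qcReport <- function(lfc, base, library, excluded = NULL) {
  rep_r <- tryCatch(replicateCorrelation(lfc), comboscreen_error = function(e) NULL)
  sep <- tryCatch(controlSeparation(base, library), comboscreen_error = function(e) NULL)
  structure(list(
    replicate_correlation = rep_r,
    ortholog_concordance = orthologConcordance(base, library),
    control_separation = sep,
    n_excluded_anchors = if (is.null(excluded)) 0L else nrow(excluded),
    excluded_anchors = excluded
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Screen QC report\n")
  if (!is.null(x$replicate_correlation)) {
    cat("  replicate Pearson r:\n")
    r <- x$replicate_correlation
    for (i in seq_len(nrow(r))) {
      cat(sprintf("    %s rep%s vs rep%s: %.3f (n = %d)\n", r$condition[i],
                  r$replicate_a[i], r$replicate_b[i], r$pearson_r[i], r$n_shared[i]))
    }
  }
  o <- x$ortholog_concordance
  for (i in seq_len(nrow(o))) {
    cat(sprintf("  ortholog concordance %s: r = %.3f over %d genes\n",
                o$condition[i], o$pearson_r[i], o$n_genes[i]))
  }
  if (!is.null(x$control_separation)) {
    s <- x$control_separation
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %s: median LFC NT %.3f / essential %.3f / targeting %.3f; separation %.2f\n",
                  s$condition[i], s$median_non_targeting[i], s$median_essential[i],
                  s$median_targeting[i], s$separation[i]))
    }
  }
  cat(sprintf("  excluded anchors: %d\n", x$n_excluded_anchors))
  invisible(x)
}

#' Write / read a QC report as JSON
#'
#' @param report a \code{qc_report}.
#' @param path JSON output path.
#' @return \code{writeQcReport}: the path, invisibly; \code{readQcReport}:
#'   the report.
#' @export
writeQcReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname writeQcReport
#' @export
readQcReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("replicate_correlation", "ortholog_concordance",
               "control_separation", "excluded_anchors")) {
    if (!is.null(x[[nm]])) x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  }
  x$n_excluded_anchors <- as.integer(x$n_excluded_anchors)
  structure(x, class = "qc_report")
}
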