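# Readers, writers and the all-by-all catalog builder for dual-ortholog
# guide libraries and construct-level count tables.

.ORTHOLOG_ALIASES <- c(
  "SpCas9" = "SpCas9", "spcas9" = "SpCas9", "Sp" = "SpCas9", "sp" = "SpCas9",
  "S. pyogenes" = "SpCas9", "SaCas9" = "SaCas9", "sacas9" = "SaCas9",
  "Sa" = "SaCas9", "sa" = "SaCas9", "S. aureus" = "SaCas9"
)

.normalizeOrtholog <- function(x) {
  out <- unname(.ORTHOLOG_ALIASES[x])
  if (anyNA(out)) {
    csStop("parse_error", "unknown ortholog token(s): %s",
           paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Read a guide library TSV
#'
#' Expects a tab-separated file with a header and columns \code{guide_id},
#' \code{ortholog}, \code{category} (plus \code{target_gene}, required for
#' targeting guides, and optional \code{note}). \code{dialect} maps canonical
#' column names to the file's column names for non-standard inputs.
#'
#' @param path path to the TSV file.
#' @param dialect optional named character vector, canonical name -> file
#'   column name, e.g. \code{c(guide_id = "sgRNA")}.
#' @return A \linkS4class{GuideLibrary}; input row order is preserved.
#' @export
readGuideLibrary <- function(path, dialect = NULL) {
  raw <- .readTsv(path)
  cols <- c(guide_id = "guide_id", ortholog = "ortholog", category = "category",
            target_gene = "target_gene", note = "note")
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  for (canon in c("guide_id", "ortholog", "category")) {
    if (!cols[[canon]] %in% names(raw)) {
      csStop("parse_error", "guide library file lacks required column '%s'", cols[[canon]])
    }
  }
  g <- data.frame(
    guide_id = as.character(raw[[cols[["guide_id"]]]]),
    ortholog = .normalizeOrtholog(as.character(raw[[cols[["ortholog"]]]])),
    category = as.character(raw[[cols[["category"]]]]),
    target_gene = if (cols[["target_gene"]] %in% names(raw)) {
      as.character(raw[[cols[["target_gene"]]]])
    } else NA_character_,
    note = if (cols[["note"]] %in% names(raw)) {
      as.character(raw[[cols[["note"]]]])
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(g$guide_id)) {
    csStop("malformed_library_error", "duplicate guide_id: %s",
           paste(unique(g$guide_id[duplicated(g$guide_id)]), collapse = ", "))
  }
  tryCatch(GuideLibrary(g), error = function(e) {
    csStop("malformed_library_error", "invalid guide library: %s", conditionMessage(e))
  })
}

#' Write a guide library TSV
#'
#' @param library a \linkS4class{GuideLibrary}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeGuideLibrary <- function(library, path) {
  .writeTsv(guides(library)[, c("guide_id", "ortholog", "category", "target_gene", "note")],
            path)
}

# Pair-class rules: only category == "targeting" contributes a gene side;
# non-targeting, essential-control and safe-harbor guides are control sides.
.classifyPairs <- function(sp_cat, sa_cat, sp_gene, sa_gene) {
  sp_t <- sp_cat == "targeting"
  sa_t <- sa_cat == "targeting"
  cls <- ifelse(sp_t & sa_t,
                ifelse(sp_gene == sa_gene, "same_gene", "gene_gene"),
                ifelse(sp_t | sa_t, "gene_control", "control_control"))
  gi <- ifelse(sp_t & sa_t, pmin(sp_gene, sa_gene),
               ifelse(sp_t, sp_gene, ifelse(sa_t, sa_gene, NA_character_)))
  gj <- ifelse(sp_t & sa_t, pmax(sp_gene, sa_gene), NA_character_)
  list(pair_class = cls, gene_i = gi, gene_j = gj)
}

#' Build the all-by-all construct catalog
#'
#' Crosses every SpCas9 guide with every SaCas9 guide, so the catalog has
#' (number of Sp guides) x (number of Sa guides) constructs — e.g. 552 x 552
#' guides give 304,704 constructs. Each construct is labeled with a pair
#' class: \code{gene_gene} (two targeting guides, distinct genes),
#' \code{same_gene}, \code{gene_control} or \code{control_control}.
#'
#' @param library a \linkS4class{GuideLibrary} with at least one guide per
#'   ortholog.
#' @return A \linkS4class{ConstructCatalog}; \code{construct_id} is
#'   \code{"<sp_guide_id>;<sa_guide_id>"}.
#' @export
buildAllByAllCatalog <- function(library) {
  g <- guides(library)
  sp <- g[g$ortholog == "SpCas9", , drop = FALSE]
  sa <- g[g$ortholog == "SaCas9", , drop = FALSE]
  if (nrow(sp) == 0L || nrow(sa) == 0L) {
    csStop("malformed_library_error", "library has no %s guides",
           if (nrow(sp) == 0L) "SpCas9" else "SaCas9")
  }
  i <- rep(seq_len(nrow(sp)), times = nrow(sa))
  j <- rep(seq_len(nrow(sa)), each = nrow(sp))
  k <- data.frame(
    construct_id = paste(sp$guide_id[i], sa$guide_id[j], sep = ";"),
    sp_guide_id = sp$guide_id[i], sa_guide_id = sa$guide_id[j],
    sp_category = sp$category[i], sa_category = sa$category[j],
    sp_gene = sp$target_gene[i], sa_gene = sa$target_gene[j],
    stringsAsFactors = FALSE
  )
  cls <- .classifyPairs(k$sp_category, k$sa_category, k$sp_gene, k$sa_gene)
  k$pair_class <- cls$pair_class
  k$gene_i <- cls$gene_i
  k$gene_j <- cls$gene_j
  new("ConstructCatalog", constructs = k)
}

#' Read a sample sheet TSV
#'
#' Columns: \code{sample_id}, \code{condition} (cell line or \code{"pDNA"}),
#' \code{replicate}, \code{timepoint_days}, and optional \code{is_reference}
#' (defaults to \code{condition == "pDNA"}). Exactly the reference samples
#' designated here are used as the LFC denominator.
#'
#' @param path path to the TSV file.
#' @return data.frame of sample annotations.
#' @export
readSampleSheet <- function(path) {
  s <- .readTsv(path)
  req <- c("sample_id", "condition", "replicate", "timepoint_days")
  if (!all(req %in% names(s))) {
    csStop("parse_error", "sample sheet lacks column(s): %s",
           paste(setdiff(req, names(s)), collapse = ", "))
  }
  if (!"is_reference" %in% names(s)) {
    s$is_reference <- s$condition == "pDNA"
  } else if (!is.logical(s$is_reference)) {
    s$is_reference <- as.logical(toupper(as.character(s$is_reference)))
  }
  if (anyDuplicated(s$sample_id)) csStop("parse_error", "duplicate sample_id in sample sheet")
  if (!any(s$is_reference)) {
    csStop("parse_error", "sample sheet designates no reference (pDNA) sample")
  }
  s
}

#' Assemble a screen count object
#'
#' Wraps a constructs x samples integer count matrix as a
#' \code{SummarizedExperiment} with the catalog annotation as
#' \code{rowData} and the sample sheet as \code{colData}.
#'
#' @param counts integer matrix, rownames = construct_id, colnames =
#'   sample_id.
#' @param catalog a \linkS4class{ConstructCatalog} covering the rows.
#' @param samples sample sheet data.frame (see \code{\link{readSampleSheet}}).
#' @return A \code{SummarizedExperiment} with assay \code{"counts"}.
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @export
screenCounts <- function(counts, catalog, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    csStop("parse_error", "count matrix needs construct_id rownames and sample_id colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    csStop("parse_error", "counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  k <- constructs(catalog)
  miss <- setdiff(rownames(counts), k$construct_id)
  if (length(miss)) {
    csStop("parse_error", "construct(s) absent from catalog: %s",
           paste(utils::head(miss, 5L), collapse = ", "))
  }
  rd <- k[match(rownames(counts), k$construct_id), , drop = FALSE]
  miss <- setdiff(samples$sample_id, colnames(counts))
  counts <- counts[, samples$sample_id[samples$sample_id %in% colnames(counts)], drop = FALSE]
  if (length(miss)) {
    csStop("parse_error", "sample(s) in sheet absent from counts: %s",
           paste(miss, collapse = ", "))
  }
  cd <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(rd, row.names = rd$construct_id),
    colData = DataFrame(cd, row.names = cd$sample_id)
  )
}

#' Read a construct count TSV against a catalog
#'
#' The counts file has a \code{construct_id} column plus one integer column
#' per sample. Rows whose construct is not in the catalog are dropped with a
#' warning; cataloged constructs absent from the file are added with count 0
#' and flagged in \code{rowData()$imputed_zero}. Sample columns must all be
#' declared in the sample sheet.
#'
#' @param path counts TSV path.
#' @param catalog a \linkS4class{ConstructCatalog}.
#' @param sample_sheet path to a sample sheet TSV, or a data.frame.
#' @return A \code{SummarizedExperiment} (see \code{\link{screenCounts}}).
#' @export
readCounts <- function(path, catalog, sample_sheet) {
  raw <- .readTsv(path)
  if (!"construct_id" %in% names(raw)) {
    csStop("parse_error", "counts file lacks a construct_id column")
  }
  samples <- if (is.character(sample_sheet)) readSampleSheet(sample_sheet) else sample_sheet
  miss <- setdiff(setdiff(names(raw), "construct_id"), samples$sample_id)
  if (length(miss)) {
    csStop("parse_error", "count column(s) absent from sample sheet: %s",
           paste(miss, collapse = ", "))
  }
  mat <- as.matrix(raw[, setdiff(names(raw), "construct_id"), drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat) || any(mat < 0) || any(mat != round(mat))) {
    bad <- which(!is.finite(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)[1L, , drop = TRUE]
    csStop("parse_error",
           "non-integer or negative count at construct '%s', sample '%s'",
           raw$construct_id[bad[[1L]]], colnames(mat)[bad[[2L]]])
  }
  rownames(mat) <- raw$construct_id
  k <- constructs(catalog)
  extra <- setdiff(rownames(mat), k$construct_id)
  if (length(extra)) {
    csWarn("dropping %d count row(s) not in catalog (e.g. %s)",
           length(extra), extra[1L])
    mat <- mat[!rownames(mat) %in% extra, , drop = FALSE]
  }
  missing_constructs <- setdiff(k$construct_id, rownames(mat))
  if (length(missing_constructs)) {
    csWarn("%d cataloged construct(s) missing from counts; filled with 0 and flagged",
           length(missing_constructs))
    fill <- matrix(0L, nrow = length(missing_constructs), ncol = ncol(mat),
                   dimnames = list(missing_constructs, colnames(mat)))
    mat <- rbind(mat, fill)
  }
  mat <- mat[k$construct_id, , drop = FALSE]
  se <- screenCounts(mat, catalog, samples)
  SummarizedExperiment::rowData(se)$imputed_zero <-
    rownames(se) %in% missing_constructs
  se
}

#' Write a count matrix TSV
#'
#' @param counts a \code{SummarizedExperiment} from \code{\link{screenCounts}}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeCounts <- function(counts, path) {
  m <- SummarizedExperiment::assay(counts, "counts")
  .writeTsv(data.frame(construct_id = rownames(m), m, check.names = FALSE), path)
}

#' Write a sample sheet TSV
#'
#' @param samples sample sheet data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeSampleSheet <- function(samples, path) {
  .writeTsv(samples, path)
}
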