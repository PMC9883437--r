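# Normalization of construct counts to log2 reads-per-million and log2 fold
# changes against the plasmid-pool (pDNA) reference.

#' Log2 reads-per-million normalization
#'
#' Converts each sample's counts to \code{log2(count / column_total * 1e6 +
#' pseudocount)}. The pseudocount (default 1 RPM) keeps zero counts finite;
#' RPM scaling makes the value invariant to sequencing depth.
#'
#' @param counts a \code{SummarizedExperiment} with assay \code{"counts"}.
#' @param pseudocount positive number added on the RPM scale before log2.
#' @return The same object with an added assay \code{"log2rpm"}.
#' @export
countsToLog2RPM <- function(counts, pseudocount = 1) {
  if (pseudocount <= 0) csStop("config_error", "pseudocount must be positive")
  m <- SummarizedExperiment::assay(counts, "counts")
  tot <- colSums(m)
  if (any(tot == 0)) {
    csStop("parse_error", "sample(s) with zero total counts: %s",
           paste(colnames(m)[tot == 0], collapse = ", "))
  }
  l2 <- log2(sweep(m, 2L, tot, "/") * 1e6 + pseudocount)
  SummarizedExperiment::assays(counts)$log2rpm <- l2
  S4Vectors::metadata(counts)$pseudocount <- pseudocount
  counts
}

#' Construct log2 fold changes versus the reference
#'
#' Subtracts the (replicate-averaged) reference log2 RPM from every
#' non-reference sample: \code{LFC = log2rpm(sample) - log2rpm(reference)}.
#' Multiple reference samples are averaged on the log2 RPM scale (equal
#' weight regardless of depth), not summed as counts.
#'
#' @param counts a \code{SummarizedExperiment} with assay \code{"log2rpm"}
#'   and a logical \code{is_reference} column in \code{colData}.
#' @return A \code{SummarizedExperiment} of the non-reference samples with
#'   assay \code{"lfc"}; metadata records the pseudocount and reference
#'   sample ids.
#' @export
computeLfc <- function(counts) {
  if (!"log2rpm" %in% SummarizedExperiment::assayNames(counts)) {
    counts <- countsToLog2RPM(counts)
  }
  cd <- SummarizedExperiment::colData(counts)
  if (!"is_reference" %in% names(cd) || !any(cd$is_reference)) {
    csStop("config_error", "no reference (pDNA) sample designated in colData")
  }
  l2 <- SummarizedExperiment::assay(counts, "log2rpm")
  ref_ids <- rownames(cd)[cd$is_reference]
  ref <- rowMeans(l2[, ref_ids, drop = FALSE])
  keep <- !cd$is_reference
  lfc <- l2[, keep, drop = FALSE] - ref
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lfc = lfc),
    rowData = SummarizedExperiment::rowData(counts),
    colData = cd[keep, , drop = FALSE]
  )
  S4Vectors::metadata(out) <- list(
    pseudocount = S4Vectors::metadata(counts)$pseudocount,
    reference_samples = ref_ids
  )
  out
}

#' Average replicate LFCs within conditions
#'
#' Arithmetic mean of per-replicate LFC columns for each condition; single
#' replicates pass through. The replicate count per condition is recorded in
#' \code{colData()$n_replicates}.
#'
#' @param lfc a \code{SummarizedExperiment} with assay \code{"lfc"} and a
#'   \code{condition} column in \code{colData}.
#' @return A \code{SummarizedExperiment} with one column per condition.
#' @export
averageReplicates <- function(lfc) {
  cd <- SummarizedExperiment::colData(lfc)
  m <- SummarizedExperiment::assay(lfc, "lfc")
  conds <- unique(as.character(cd$condition))
  avg <- vapply(conds, function(cc) {
    rowMeans(m[, cd$condition == cc, drop = FALSE])
  }, numeric(nrow(m)))
  avg <- matrix(avg, nrow = nrow(m), dimnames = list(rownames(m), conds))
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lfc = avg),
    rowData = SummarizedExperiment::rowData(lfc),
    colData = S4Vectors::DataFrame(
      sample_id = conds, condition = conds,
      n_replicates = as.integer(table(cd$condition)[conds]),
      row.names = conds
    )
  )
  S4Vectors::metadata(out) <- S4Vectors::metadata(lfc)
  out
}

#' Write an LFC table TSV
#'
#' Emits construct_id, the two guide ids, and one column per sample or
#' condition.
#'
#' @param lfc a \code{SummarizedExperiment} with assay \code{"lfc"}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeLfc <- function(lfc, path) {
  rd <- SummarizedExperiment::rowData(lfc)
  m <- SummarizedExperiment::assay(lfc, "lfc")
  .writeTsv(data.frame(construct_id = rownames(m),
                       sp_guide_id = rd$sp_guide_id,
                       sa_guide_id = rd$sa_guide_id,
                       m, check.names = FALSE), path)
}
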