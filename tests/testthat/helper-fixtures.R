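# Fixtures built in code: tiny libraries, catalogs and LFC containers.

simpleLibrary <- function(genes = c("A", "B", "C"), guides_per_gene = 1L,
                          n_nt = 2L, n_ess = 0L) {
  mk <- function(prefix, ortholog) {
    tg <- data.frame(
      guide_id = sprintf("%s_%s_%d", prefix, rep(genes, each = guides_per_gene),
                         rep(seq_len(guides_per_gene), times = length(genes))),
      ortholog = ortholog, category = "targeting",
      target_gene = rep(genes, each = guides_per_gene),
      stringsAsFactors = FALSE
    )
    nt <- if (n_nt > 0L) data.frame(
      guide_id = sprintf("%s_nt%d", prefix, seq_len(n_nt)),
      ortholog = ortholog, category = "non_targeting",
      target_gene = NA_character_, stringsAsFactors = FALSE
    ) else NULL
    ess <- if (n_ess > 0L) data.frame(
      guide_id = sprintf("%s_ess%d", prefix, seq_len(n_ess)),
      ortholog = ortholog, category = "essential_control",
      target_gene = sprintf("ESS%d", seq_len(n_ess)), stringsAsFactors = FALSE
    ) else NULL
    rbind(tg, nt, ess)
  }
  GuideLibrary(rbind(mk("sp", "SpCas9"), mk("sa", "SaCas9")))
}

# LFC container with catalog annotation, as the scoring functions expect.
lfcSE <- function(m, catalog, conditions = colnames(m)) {
  k <- constructs(catalog)
  stopifnot(all(rownames(m) %in% k$construct_id))
  rd <- k[match(rownames(m), k$construct_id), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lfc = m),
    rowData = S4Vectors::DataFrame(rd, row.names = rownames(m)),
    colData = S4Vectors::DataFrame(sample_id = colnames(m),
                                   condition = conditions,
                                   replicate = seq_len(ncol(m)),
                                   n_replicates = 1L, row.names = colnames(m))
  )
  S4Vectors::metadata(se) <- list(pseudocount = 1, reference_samples = "ref")
  se
}

# Full-catalog LFC matrix initialised to a constant.
lfcMatrix <- function(catalog, samples = "s1", fill = 0) {
  k <- constructs(catalog)
  matrix(fill, nrow = nrow(k), ncol = length(samples),
         dimnames = list(k$construct_id, samples))
}

sampleSheet <- function(sample_ids, condition, replicate = seq_along(sample_ids),
                        timepoint = 21, is_reference = FALSE) {
  data.frame(sample_id = sample_ids, condition = condition,
             replicate = replicate, timepoint_days = timepoint,
             is_reference = rep_len(is_reference, length(sample_ids)),
             stringsAsFactors = FALSE)
}

# A ready-made counts object: one pDNA reference plus endpoint samples.
countsSE <- function(mat, catalog, n_ref = 1L, condition = "cells") {
  ids <- colnames(mat)
  sheet <- sampleSheet(
    ids, condition = c(rep("pDNA", n_ref), rep(condition, ncol(mat) - n_ref)),
    replicate = c(seq_len(n_ref), seq_len(ncol(mat) - n_ref)),
    timepoint = c(rep(0, n_ref), rep(21, ncol(mat) - n_ref)),
    is_reference = c(rep(TRUE, n_ref), rep(FALSE, ncol(mat) - n_ref))
  )
  screenCounts(mat, catalog, sheet)
}
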