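# Hit calling: synergistic-lethal / compensatory-non-lethal / buffering /
# neutral labels from gene-pair interaction z-scores and lethality cuts,
# with a normal-tail + Benjamini-Hochberg FDR and per-pair rank-sum tests.

.HIT_LABELS <- c("synergistic_lethal", "synergistic_nonlethal",
                 "compensatory_non_lethal", "buffering", "neutral")

#' Single-knockout LFC per gene
#'
#' Mean LFC across all constructs pairing any of a gene's guides with
#' opposite-ortholog negative controls, both Cas9 orientations pooled —
#' e.g. 4 guides x 14 non-targeting partners give 56 gene-control
#' constructs per gene.
#'
#' @param lfc a \code{SummarizedExperiment} with assay \code{"lfc"} and
#'   catalog annotation in \code{rowData}.
#' @param control_categories negative-control partner categories.
#' @return data.frame(condition, gene, single_ko_lfc, n_constructs).
#' @export
singleKoLfc <- function(lfc, control_categories = "non_targeting") {
  rd <- as.data.frame(SummarizedExperiment::rowData(lfc))
  m <- SummarizedExperiment::assay(lfc, "lfc")
  rows_sp <- rd$sp_category == "targeting" & rd$sa_category %in% control_categories
  rows_sa <- rd$sa_category == "targeting" & rd$sp_category %in% control_categories
  if (!any(rows_sp) && !any(rows_sa)) {
    csStop("config_error", "no gene_control constructs with the given control categories")
  }
  gene <- c(rd$sp_gene[rows_sp], rd$sa_gene[rows_sa])
  vals <- rbind(m[rows_sp, , drop = FALSE], m[rows_sa, , drop = FALSE])
  sums <- rowsum(vals, gene, reorder = FALSE)
  n <- as.integer(.groupSum(rep(1, length(gene)), gene))
  means <- sweep(sums, 1L, n, "/")
  data.frame(
    condition = rep(colnames(m), each = nrow(means)),
    gene = rep(rownames(means), times = ncol(means)),
    single_ko_lfc = as.vector(means),
    n_constructs = rep(n, times = ncol(means)),
    stringsAsFactors = FALSE
  )
}

#' Screen-average gene-pair LFC
#'
#' Arithmetic mean of the per-pair mean observed LFC over distinct-gene
#' pairs (\code{gene_gene} only; same-gene pairs excluded), per condition.
#' This is the default lethality cut — the dotted-line average a depletion
#' scatter is drawn at.
#'
#' @param scores gene-pair score table from \code{\link{scoreGenePairs}}.
#' @return Named numeric vector, one value per condition.
#' @export
screenAverageLfc <- function(scores) {
  s <- scores[!scores$same_gene, , drop = FALSE]
  if (nrow(s) == 0L) csStop("config_error", "no distinct-gene pairs to average")
  vapply(split(s$mean_observed_lfc, s$condition), mean, numeric(1L))
}

#' Depletion p-values and BH q-values for gene pairs
#'
#' One-sided (depletion) p-value from the lower standard-normal tail of
#' \code{z_gene}; Benjamini-Hochberg q-values over all distinct-gene pairs
#' within each condition (same-gene pairs get a p-value but no q-value).
#'
#' @param scores gene-pair score table.
#' @return The table with added \code{p_value} and \code{fdr_q} columns.
#' @export
computeFdr <- function(scores) {
  scores$p_value <- stats::pnorm(scores$z_gene)
  scores$fdr_q <- NA_real_
  for (cc in unique(scores$condition)) {
    idx <- which(scores$condition == cc & !scores$same_gene)
    scores$fdr_q[idx] <- stats::p.adjust(scores$p_value[idx], method = "BH")
  }
  scores
}

#' Classify gene pairs into interaction phenotypes
#'
#' A pair with \code{z_gene < z_cut} is synergistic; it is
#' \code{synergistic_lethal} when its mean observed LFC falls below the
#' lethality cut (default: the screen-average pair LFC of its condition),
#' \code{compensatory_non_lethal} when it stays at or above the cut and both
#' single knockouts improve fitness (single-KO LFC above
#' \code{positivity_cut}), and \code{synergistic_nonlethal} otherwise.
#' \code{z_gene > |z_cut|} is \code{buffering}; everything else
#' \code{neutral}. Pairs missing a single-KO estimate keep their synergy
#' status, skip the compensation test and are flagged.
#'
#' @param scores gene-pair score table (p/q columns added if absent).
#' @param single_ko table from \code{\link{singleKoLfc}}, or NULL to skip
#'   compensation calls.
#' @param z_cut synergy threshold on \code{z_gene} (default -4).
#' @param lethality_cut numeric cut, or NULL for the per-condition screen
#'   average.
#' @param positivity_cut single-KO LFC above which a knockout counts as
#'   fitness-improving (default 0.5).
#' @param include_same_gene score same-gene pairs too (default FALSE).
#' @return Hit-call data.frame with label, thresholds and flags.
#' @export
classifyPairs <- function(scores, single_ko = NULL, z_cut = -4,
                          lethality_cut = NULL, positivity_cut = 0.5,
                          include_same_gene = FALSE) {
  if (!"p_value" %in% names(scores)) scores <- computeFdr(scores)
  if (is.null(lethality_cut)) {
    cuts <- screenAverageLfc(scores)
  } else {
    conds <- unique(scores$condition)
    cuts <- stats::setNames(rep_len(lethality_cut, length(conds)), conds)
  }
  h <- if (include_same_gene) scores else scores[!scores$same_gene, , drop = FALSE]
  h$lethality_cut <- unname(cuts[h$condition])
  if (!is.null(single_ko)) {
    ki <- match(paste(h$condition, h$gene_i), paste(single_ko$condition, single_ko$gene))
    kj <- match(paste(h$condition, h$gene_j), paste(single_ko$condition, single_ko$gene))
    h$single_ko_lfc_i <- single_ko$single_ko_lfc[ki]
    h$single_ko_lfc_j <- single_ko$single_ko_lfc[kj]
  } else {
    h$single_ko_lfc_i <- NA_real_
    h$single_ko_lfc_j <- NA_real_
  }
  singles_known <- is.finite(h$single_ko_lfc_i) & is.finite(h$single_ko_lfc_j)
  lethal <- h$mean_observed_lfc < h$lethality_cut
  compens <- !lethal & singles_known &
    h$single_ko_lfc_i > positivity_cut & h$single_ko_lfc_j > positivity_cut
  h$label <- ifelse(
    h$z_gene < z_cut,
    ifelse(lethal, "synergistic_lethal",
           ifelse(compens, "compensatory_non_lethal", "synergistic_nonlethal")),
    ifelse(h$z_gene > abs(z_cut), "buffering", "neutral")
  )
  h$z_cut <- z_cut
  h$positivity_cut <- positivity_cut
  flags <- character(nrow(h))
  flags[!singles_known] <- "missing_single_ko"
  if ("asymmetric" %in% names(h)) {
    flags[h$asymmetric] <- trimws(paste(flags[h$asymmetric], "asymmetric"))
  }
  if (include_same_gene && "same_gene" %in% names(h)) {
    flags[h$same_gene] <- trimws(paste(flags[h$same_gene], "same_gene"))
  }
  h$flags <- flags
  rownames(h) <- NULL
  h
}

#' Two-tailed Mann-Whitney test for one gene pair
#'
#' Rank-sum comparison of a gene pair's construct LFCs against the two
#' genes' gene-control construct LFCs. Exact when both groups have at most
#' 8 observations and no ties; otherwise the normal approximation with tie
#' correction. Group sizes such as 8 pair constructs versus 56 gene-control
#' constructs are the intended use.
#'
#' @param pair_lfcs per-construct LFCs of the gene pair.
#' @param control_lfcs per-construct LFCs of the genes' control pairings.
#' @return list(u, p_value, exact).
#' @export
mannWhitneyPairTest <- function(pair_lfcs, control_lfcs) {
  if (length(pair_lfcs) == 0L || length(control_lfcs) == 0L) {
    csStop("config_error", "both groups must be non-empty")
  }
  exact <- length(pair_lfcs) <= 8L && length(control_lfcs) <= 8L &&
    !anyDuplicated(c(pair_lfcs, control_lfcs))
  wt <- suppressWarnings(stats::wilcox.test(
    pair_lfcs, control_lfcs, alternative = "two.sided",
    exact = exact, correct = FALSE
  ))
  list(u = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Top synergistic-lethal hits
#'
#' Synergistic-lethal pairs ordered by ascending \code{z_gene}, ties broken
#' by ascending mean observed LFC, then lexicographic gene pair; the first
#' \code{k} are returned (all of them, with a message, if fewer exist).
#'
#' @param hitcalls hit-call table from \code{\link{classifyPairs}}.
#' @param k number of hits to return.
#' @return Ordered data.frame of at most \code{k} hits.
#' @export
rankTopHits <- function(hitcalls, k) {
  if (k < 1L) csStop("config_error", "k must be >= 1")
  h <- hitcalls[hitcalls$label == "synergistic_lethal", , drop = FALSE]
  h <- h[order(h$z_gene, h$mean_observed_lfc, h$gene_i, h$gene_j), , drop = FALSE]
  if (nrow(h) < k) {
    message(sprintf("only %d synergistic_lethal hit(s) available (k = %d)", nrow(h), k))
  }
  utils::head(h, k)
}

#' Write a hit-call TSV and run-metadata sidecar
#'
#' @param hitcalls hit-call table.
#' @param path output TSV path; a JSON sidecar with the thresholds used is
#'   written next to it as \code{<path>.meta.json}.
#' @param extra optional named list merged into the sidecar.
#' @return The path, invisibly.
#' @export
writeHitCalls <- function(hitcalls, path, extra = list()) {
  .writeTsv(hitcalls, path)
  meta <- c(list(
    z_cut = unique(hitcalls$z_cut),
    lethality_cut = stats::setNames(
      as.list(unique(hitcalls$lethality_cut)),
      unique(hitcalls$condition)[seq_along(unique(hitcalls$lethality_cut))]
    ),
    positivity_cut = unique(hitcalls$positivity_cut),
    fdr_method = "one-sided normal lower tail + Benjamini-Hochberg",
    labels = .HIT_LABELS
  ), extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
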