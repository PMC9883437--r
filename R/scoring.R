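# Genetic-interaction scoring: per-guide base (single-knockout) LFCs,
# per-anchor-sgRNA linear fits of combination LFCs against partner base
# LFCs, within-anchor residual z-scores, and gene-pair aggregation.
#
# For an anchor guide i the expected LFC of its combination with partner j
# is the fitted line yhat_ij = m_i * x_j + b_i, where x_j is partner j's
# base LFC (its mean LFC when paired with negative controls). Residuals
# y_ij - yhat_ij are z-scored within the anchor; gene-pair scores sum z_ij
# over the pair's constructs in each anchor orientation, divide by the
# square root of the construct count, sum the two orientations and divide
# by sqrt(2).

#' Per-guide base LFCs from control pairings
#'
#' A guide's base LFC is its mean LFC across constructs pairing it with
#' opposite-ortholog negative-control guides — its single-knockout fitness
#' estimate and the regressor of the anchor model.
#'
#' @param lfc a \code{SummarizedExperiment} with assay \code{"lfc"} and
#'   catalog annotation in \code{rowData} (see \code{\link{computeLfc}}).
#' @param control_categories guide categories counted as negative controls
#'   (default non-targeting only; safe-harbor guides are excluded unless
#'   added here).
#' @return data.frame(condition, guide_id, ortholog, base_lfc,
#'   n_control_partners), one row per guide and condition. Guides with no
#'   control pairing are omitted (ids in \code{attr(, "omitted")}).
#' @export
computeBaseLfc <- function(lfc, control_categories = "non_targeting") {
  rd <- as.data.frame(SummarizedExperiment::rowData(lfc))
  m <- SummarizedExperiment::assay(lfc, "lfc")
  rows_sp <- rd$sa_category %in% control_categories   # Sa side is the control
  rows_sa <- rd$sp_category %in% control_categories   # Sp side is the control
  if (!any(rows_sp) && !any(rows_sa)) {
    csStop("config_error", "catalog contains no guides of control category: %s",
           paste(control_categories, collapse = ", "))
  }
  guide <- c(rd$sp_guide_id[rows_sp], rd$sa_guide_id[rows_sa])
  ortho <- c(rep("SpCas9", sum(rows_sp)), rep("SaCas9", sum(rows_sa)))
  vals <- rbind(m[rows_sp, , drop = FALSE], m[rows_sa, , drop = FALSE])
  sums <- rowsum(vals, guide, reorder = FALSE)
  n <- as.integer(.groupSum(rep(1, length(guide)), guide))
  ortho <- ortho[!duplicated(guide)]
  base <- sweep(sums, 1L, n, "/")
  out <- data.frame(
    condition = rep(colnames(m), each = nrow(base)),
    guide_id = rep(rownames(sums), times = ncol(base)),
    ortholog = rep(ortho, times = ncol(base)),
    base_lfc = as.vector(base),
    n_control_partners = rep(n, times = ncol(base)),
    stringsAsFactors = FALSE
  )
  all_guides <- unique(c(rd$sp_guide_id, rd$sa_guide_id))
  omitted <- setdiff(all_guides, rownames(sums))
  if (length(omitted)) {
    csWarn("%d guide(s) have no control pairing and get no base LFC (e.g. %s)",
           length(omitted), omitted[1L])
  }
  attr(out, "omitted") <- omitted
  out
}

#' Ordinary least-squares fit for one anchor sgRNA
#'
#' Closed-form OLS of combination LFCs (y) on partner base LFCs (x):
#' slope = cov(x, y) / var(x), intercept = mean(y) - slope * mean(x).
#'
#' @param x partner base LFCs.
#' @param y observed combination LFCs, same length.
#' @param sd_tol tolerance below which var(x) is treated as degenerate.
#' @return list(slope, intercept, n_points, residuals, residual_mean,
#'   residual_sd); residual_sd uses the sample (n - 1) denominator.
#' @export
fitAnchorModel <- function(x, y, sd_tol = 1e-8) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) csStop("degenerate_fit_error", "anchor fit needs at least 2 points")
  if (stats::sd(x) < sd_tol) {
    csStop("degenerate_fit_error", "zero-variance regressor: all partner base LFCs equal")
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (slope * x + intercept)
  list(slope = slope, intercept = intercept, n_points = n, residuals = res,
       residual_mean = mean(res), residual_sd = stats::sd(res))
}

#' Z-score residuals within one anchor
#'
#' \code{z = (residual - mean(residual)) / sd(residual)} with the sample
#' (n - 1) standard deviation. If the residual spread is below
#' \code{sd_tol} all z are set to 0 and the result carries
#' \code{attr(, "degenerate") = TRUE}.
#'
#' @param residuals numeric vector of at least 2 residuals.
#' @param sd_tol degenerate-spread guard.
#' @return numeric z vector.
#' @export
zscoreResiduals <- function(residuals, sd_tol = 1e-8) {
  if (length(residuals) < 2L) {
    csStop("degenerate_fit_error", "z-scoring needs at least 2 residuals")
  }
  s <- stats::sd(residuals)
  if (!is.finite(s) || s < sd_tol) {
    z <- rep(0, length(residuals))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  z <- (residuals - mean(residuals)) / s
  attr(z, "degenerate") <- FALSE
  z
}

# Long table of (anchor, partner) observations: both orientations of every
# targeting x targeting construct whose partner has a defined base LFC.
.anchorLongTable <- function(rd, m, base) {
  tt <- rd$sp_category == "targeting" & rd$sa_category == "targeting"
  k <- rd[tt, , drop = FALSE]
  conds <- colnames(m)
  pieces <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    cc <- conds[ci]
    b <- base[base$condition == cc, , drop = FALSE]
    bmap <- stats::setNames(b$base_lfc, b$guide_id)
    y <- m[tt, ci]
    long <- data.frame(
      condition = cc,
      anchor_guide = c(k$sp_guide_id, k$sa_guide_id),
      anchor_gene = c(k$sp_gene, k$sa_gene),
      partner_guide = c(k$sa_guide_id, k$sp_guide_id),
      partner_gene = c(k$sa_gene, k$sp_gene),
      construct_id = c(k$construct_id, k$construct_id),
      y = c(y, y),
      stringsAsFactors = FALSE
    )
    long$x <- unname(bmap[long$partner_guide])
    pieces[[ci]] <- long[is.finite(long$x) & is.finite(long$y), , drop = FALSE]
  }
  do.call(rbind, pieces)
}

#' Fit the anchor regression for every sgRNA
#'
#' For each condition and each targeting anchor guide, regresses the LFCs of
#' the anchor's combinations with other targeting guides on the partners'
#' base LFCs, then z-scores the residuals within the anchor. Anchors with
#' fewer than \code{min_points} usable partners or a zero-variance regressor
#' are excluded and reported. Constructs whose partner guide lacks a base
#' LFC are excluded from the fit.
#'
#' @param lfc a \code{SummarizedExperiment} with assay \code{"lfc"} and
#'   catalog annotation in \code{rowData}.
#' @param base per-guide base LFC table from \code{\link{computeBaseLfc}}.
#' @param min_points minimum partners per anchor (default 10).
#' @param sd_tol degenerate-variance guard for regressor and residual sd.
#' @return list with elements \code{fits} (condition, anchor_guide,
#'   anchor_gene, slope, intercept, n_points, residual_mean, residual_sd,
#'   degenerate_sd), \code{z} (one row per anchor-partner observation with
#'   x, y, yhat, residual, z) and \code{excluded} (anchor, reason).
#' @export
fitAnchorModels <- function(lfc, base, min_points = 10, sd_tol = 1e-8) {
  rd <- as.data.frame(SummarizedExperiment::rowData(lfc))
  m <- SummarizedExperiment::assay(lfc, "lfc")
  long <- .anchorLongTable(rd, m, base)
  if (is.null(long) || nrow(long) == 0L) {
    csStop("config_error", "no targeting x targeting constructs with defined partner base LFCs")
  }
  key <- paste(long$condition, long$anchor_guide, sep = "\r")
  n <- .groupSum(rep(1, nrow(long)), key)
  sx <- .groupSum(long$x, key)
  sy <- .groupSum(long$y, key)
  sxx <- .groupSum(long$x^2, key)
  sxy <- .groupSum(long$x * long$y, key)
  vx <- (sxx - sx^2 / n) / pmax(n - 1, 1)
  ok_n <- n >= min_points
  ok_v <- vx > sd_tol^2
  keep_anchor <- ok_n & ok_v
  reason <- ifelse(!ok_n, "too_few_partners", ifelse(!ok_v, "degenerate_regressor", NA))
  ex_keys <- names(n)[!keep_anchor]
  excluded <- data.frame(
    condition = sub("\r.*$", "", ex_keys),
    anchor_guide = sub("^.*\r", "", ex_keys),
    n_points = as.integer(n[!keep_anchor]),
    reason = reason[!keep_anchor],
    stringsAsFactors = FALSE
  )
  if (nrow(excluded)) {
    csWarn("excluded %d anchor fit(s): %s", nrow(excluded),
           paste(sprintf("%s (n=%d)", names(table(excluded$reason)),
                         as.integer(table(excluded$reason))), collapse = ", "))
  }
  slope <- (sxy - sx * sy / n) / (sxx - sx^2 / n)
  intercept <- sy / n - slope * sx / n
  rows_keep <- keep_anchor[key]
  long <- long[rows_keep, , drop = FALSE]
  key <- key[rows_keep]
  long$yhat <- slope[key] * long$x + intercept[key]
  long$residual <- long$y - long$yhat
  # per-anchor residual mean/sd via grouped sums
  nn <- n[unique(key)]
  rsum <- .groupSum(long$residual, key)
  rsq <- .groupSum(long$residual^2, key)
  mu <- rsum / nn[names(rsum)]
  ssd <- sqrt(pmax(rsq - rsum^2 / nn[names(rsum)], 0) / pmax(nn[names(rsum)] - 1, 1))
  degen <- ssd < sd_tol
  z <- (long$residual - mu[key]) / ifelse(degen[key], 1, ssd[key])
  z[degen[key]] <- 0
  long$z <- z
  fit_keys <- names(rsum)
  fits <- data.frame(
    condition = sub("\r.*$", "", fit_keys),
    anchor_guide = sub("^.*\r", "", fit_keys),
    slope = unname(slope[fit_keys]),
    intercept = unname(intercept[fit_keys]),
    n_points = as.integer(nn[fit_keys]),
    residual_mean = unname(mu[fit_keys]),
    residual_sd = unname(ssd[fit_keys]),
    degenerate_sd = unname(degen[fit_keys]),
    stringsAsFactors = FALSE
  )
  fits$anchor_gene <- long$anchor_gene[match(fit_keys, key)]
  list(fits = fits, z = long, excluded = excluded)
}

#' Aggregate residual z-scores to gene-pair interaction scores
#'
#' For gene pair (I, J): \code{S_I} sums z over the pair's constructs with
#' the anchor fixed on gene I and divides by the square root of the number
#' of constructs covering the pair (both Cas9 arrangements); \code{S_J} is
#' the other orientation; \code{z_gene = (S_I + S_J) / sqrt(2)}. The result
#' is symmetric in gene order. Same-gene pairs are scored but flagged;
#' pairs observed in only one orientation are flagged asymmetric.
#'
#' @param anchor_z output of \code{\link{fitAnchorModels}} (or its \code{z}
#'   data.frame).
#' @return data.frame(condition, gene_i, gene_j, n_constructs, s_i, s_j,
#'   z_gene, mean_observed_lfc, same_gene, asymmetric).
#' @export
scoreGenePairs <- function(anchor_z) {
  z <- if (is.list(anchor_z) && !is.data.frame(anchor_z)) anchor_z$z else anchor_z
  z <- z[!is.na(z$anchor_gene) & !is.na(z$partner_gene), , drop = FALSE]
  if (nrow(z) == 0L) csStop("config_error", "no scored targeting pairs")
  gi <- pmin(z$anchor_gene, z$partner_gene)
  gj <- pmax(z$anchor_gene, z$partner_gene)
  key <- paste(z$condition, gi, gj, sep = "\r")
  sg <- z$anchor_gene == z$partner_gene
  anchor_first <- z$anchor_gene == gi & !sg
  anchor_second <- z$anchor_gene == gj & !sg
  sum_first <- .groupSum(z$z * (anchor_first + 0.5 * sg), key)
  sum_second <- .groupSum(z$z * (anchor_second + 0.5 * sg), key)
  n_first <- .groupSum(anchor_first + sg, key)
  n_second <- .groupSum(anchor_second + sg, key)
  first_obs <- !duplicated(paste(key, z$construct_id, sep = "\r"))
  n_con <- .groupSum(as.numeric(first_obs), key)
  mean_lfc <- .groupSum(z$y * first_obs, key) / n_con
  keys <- names(n_con)
  s_i <- sum_first[keys] / sqrt(n_con[keys])
  s_j <- sum_second[keys] / sqrt(n_con[keys])
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(
    condition = parts[, 1L], gene_i = parts[, 2L], gene_j = parts[, 3L],
    n_constructs = as.integer(n_con[keys]),
    s_i = unname(s_i), s_j = unname(s_j),
    z_gene = unname((s_i + s_j) / sqrt(2)),
    mean_observed_lfc = unname(mean_lfc[keys]),
    same_gene = parts[, 2L] == parts[, 3L],
    asymmetric = unname(n_first[keys] == 0 | n_second[keys] == 0) &
      parts[, 2L] != parts[, 3L],
    stringsAsFactors = FALSE
  )
  if (any(out$asymmetric)) {
    csWarn("%d gene pair(s) scored from a single anchor orientation", sum(out$asymmetric))
  }
  rownames(out) <- NULL
  out[order(out$condition, out$gene_i, out$gene_j), , drop = FALSE]
}

#' End-to-end screen scoring
#'
#' Composes the full scoring pipeline: log2 RPM normalization, LFCs versus
#' the reference, replicate averaging (optional), base LFCs, anchor fits,
#' within-anchor residual z-scores and gene-pair aggregation. Deterministic
#' given inputs and parameters.
#'
#' @param counts a \code{SummarizedExperiment} from \code{\link{screenCounts}}
#'   or \code{\link{readCounts}}.
#' @param pseudocount RPM pseudocount (see \code{\link{countsToLog2RPM}}).
#' @param control_categories negative-control categories for base LFCs.
#' @param min_points minimum partners per anchor fit.
#' @param sd_tol degenerate-variance guard.
#' @param average_replicates average replicate LFCs within conditions before
#'   scoring (default); set FALSE for per-replicate QC scoring.
#' @return Gene-pair score data.frame (see \code{\link{scoreGenePairs}});
#'   intermediates are attached as attributes \code{"lfc"}, \code{"base"}
#'   and \code{"anchor_fits"}.
#' @export
scoreScreen <- function(counts, pseudocount = 1,
                        control_categories = "non_targeting",
                        min_points = 10, sd_tol = 1e-8,
                        average_replicates = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      csStop("pipeline_error", "stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  lfc <- stage("lfc", computeLfc(countsToLog2RPM(counts, pseudocount)))
  if (average_replicates) lfc <- stage("average_replicates", averageReplicates(lfc))
  base <- stage("base_lfc", computeBaseLfc(lfc, control_categories))
  fits <- stage("anchor_fit", fitAnchorModels(lfc, base, min_points, sd_tol))
  scores <- stage("gene_pairs", scoreGenePairs(fits))
  attr(scores, "lfc") <- lfc
  attr(scores, "base") <- base
  attr(scores, "anchor_fits") <- fits[c("fits", "excluded")]
  scores
}

#' Write a gene-pair score TSV
#'
#' @param scores gene-pair score data.frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGenePairScores <- function(scores, path) {
  .writeTsv(as.data.frame(scores), path)
}
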