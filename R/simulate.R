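# Generative model of a dual-Cas9 combinatorial screen with known ground
# truth. Per-construct growth is additive in the two guides' gene fitness
# (weighted by cutting efficiency) plus an efficiency-weighted pairwise
# interaction term:
#
#   g_c = e_sp * f[G(sp)] + e_sa * f[G(sa)] + e_sp * e_sa * eps[G(sp), G(sa)]
#
# in per-doubling log2 units; controls have f = 0 and eps = 0. Endpoint
# abundance is the renormalized pDNA-weighted growth factor 2^(g_c * T), and
# reads are drawn with negative-binomial (or exact multinomial) noise.

#' Simulated screen configuration
#'
#' Builds a validated \linkS4class{SimConfig}. Defaults emulate the screened
#' study conditions: 2 guides per gene per ortholog (4 guides per gene
#' overall), 14 non-targeting guides per ortholog, growth for 21 population
#' doublings (a 21-day screen at 24 h doubling; use ~16.8 for a 30 h
#' doubler), coverage of 1000 reads per construct and duplicate endpoint
#' replicates. Noise defaults (lognormal pDNA sdlog 0.5, count dispersion
#' 0.15, efficiency Beta with mean 0.8) are calibrated so replicate LFC
#' concordance lands in the 0.93-0.95 Pearson range typical of
#' well-executed screens.
#'
#' @param n_genes number of targeted genes (named \code{G001}, \code{G002},
#'   ...).
#' @param guides_per_gene guides per gene per ortholog.
#' @param n_nt non-targeting guides per ortholog.
#' @param n_essential essential-control guides per ortholog (targeting
#'   pseudo-genes \code{ESS1}, ... with essential-like fitness).
#' @param fraction_essential fraction of target genes drawn essential-like.
#' @param fitness_essential,fitness_normal,fitness_sd per-doubling gene
#'   fitness values and across-gene jitter.
#' @param fitness_override data.frame(gene, fitness) of explicit
#'   per-doubling fitness values applied after the random draw.
#' @param interactions data.frame(gene_i, gene_j, epsilon) of injected
#'   per-doubling interaction terms (distinct genes only).
#' @param efficiency_mean,efficiency_shape Beta mean and concentration of
#'   guide cutting efficiency.
#' @param pdna_sigma sdlog of the lognormal pDNA representation.
#' @param doublings growth duration T in population doublings.
#' @param coverage reads per construct per sample.
#' @param dispersion negative-binomial count dispersion (0 = Poisson).
#' @param count_model \code{"nb"} or \code{"multinomial"} (exact depth).
#' @param n_replicates endpoint replicates.
#' @param seed master seed for all random streams.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(n_genes = 50L, guides_per_gene = 2L, n_nt = 14L,
                      n_essential = 4L, fraction_essential = 0.2,
                      fitness_essential = -0.25, fitness_normal = 0,
                      fitness_sd = 0.02,
                      fitness_override = data.frame(gene = character(),
                                                    fitness = numeric(),
                                                    stringsAsFactors = FALSE),
                      interactions = data.frame(gene_i = character(),
                                                gene_j = character(),
                                                epsilon = numeric(),
                                                stringsAsFactors = FALSE),
                      efficiency_mean = 0.8, efficiency_shape = 10,
                      pdna_sigma = 0.5, doublings = 21, coverage = 1000,
                      dispersion = 0.15, count_model = "nb",
                      n_replicates = 2L, seed = 1L) {
  new("SimConfig",
      n_genes = as.integer(n_genes), guides_per_gene = as.integer(guides_per_gene),
      n_nt = as.integer(n_nt), n_essential = as.integer(n_essential),
      fraction_essential = fraction_essential,
      fitness_essential = fitness_essential, fitness_normal = fitness_normal,
      fitness_sd = fitness_sd,
      fitness_override = as.data.frame(fitness_override, stringsAsFactors = FALSE),
      interactions = as.data.frame(interactions, stringsAsFactors = FALSE),
      efficiency_mean = efficiency_mean, efficiency_shape = efficiency_shape,
      pdna_sigma = pdna_sigma, doublings = doublings, coverage = coverage,
      dispersion = dispersion, count_model = count_model,
      n_replicates = as.integer(n_replicates), seed = as.integer(seed))
}

.simGeneNames <- function(n) sprintf("G%03d", seq_len(n))

# Library layout implied by a SimConfig (deterministic, no randomness).
.simLibrary <- function(config) {
  genes <- .simGeneNames(config@n_genes)
  mk <- function(prefix, ortholog) {
    tg <- data.frame(
      guide_id = sprintf("%s_%s_%d", prefix,
                         rep(genes, each = config@guides_per_gene),
                         rep(seq_len(config@guides_per_gene), times = length(genes))),
      ortholog = ortholog, category = "targeting",
      target_gene = rep(genes, each = config@guides_per_gene),
      note = NA_character_, stringsAsFactors = FALSE
    )
    nt <- if (config@n_nt > 0L) data.frame(
      guide_id = sprintf("%s_NT_%02d", prefix, seq_len(config@n_nt)),
      ortholog = ortholog, category = "non_targeting",
      target_gene = NA_character_, note = NA_character_,
      stringsAsFactors = FALSE
    ) else NULL
    ess <- if (config@n_essential > 0L) data.frame(
      guide_id = sprintf("%s_ESS_%02d", prefix, seq_len(config@n_essential)),
      ortholog = ortholog, category = "essential_control",
      target_gene = sprintf("ESS%d", seq_len(config@n_essential)),
      note = NA_character_, stringsAsFactors = FALSE
    ) else NULL
    rbind(tg, nt, ess)
  }
  GuideLibrary(rbind(mk("sp", "SpCas9"), mk("sa", "SaCas9")))
}

# Symmetric interaction lookup for construct gene pairs; 0 when absent or
# when either side is not a targeting guide.
.epsilonFor <- function(gene_a, gene_b, interactions) {
  if (!nrow(interactions)) return(numeric(length(gene_a)))
  key <- paste(pmin(gene_a, gene_b), pmax(gene_a, gene_b), sep = "\r")
  ikey <- paste(pmin(interactions$gene_i, interactions$gene_j),
                pmax(interactions$gene_i, interactions$gene_j), sep = "\r")
  eps <- interactions$epsilon[match(key, ikey)]
  eps[is.na(eps)] <- 0
  eps[is.na(gene_a) | is.na(gene_b)] <- 0
  eps
}

#' Simulate a pooled dual-guide screen
#'
#' Builds the all-by-all catalog for the configured library, samples pDNA
#' representation (lognormal, normalized), guide efficiencies (Beta) and
#' gene fitness, computes true per-construct growth, grows the pool for
#' \code{doublings} population doublings and draws sequencing counts at
#' depth \code{coverage * n_constructs} per sample (negative-binomial, or
#' multinomial for exact depth). All randomness derives from
#' \code{config@seed} via named substreams, so identical configs give
#' byte-identical output.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return list(library, catalog, counts, truth): a
#'   \linkS4class{GuideLibrary}, \linkS4class{ConstructCatalog}, a
#'   \code{SummarizedExperiment} of counts (pDNA reference + endpoint
#'   replicates) and a \linkS4class{SimTruth}.
#' @export
simulateScreen <- function(config) {
  validObject(config)
  lib <- .simLibrary(config)
  catalog <- buildAllByAllCatalog(lib)
  k <- constructs(catalog)
  n_con <- nrow(k)
  seeds <- deriveSeeds(config@seed,
                       c("fitness", "efficiency", "pdna",
                         sprintf("counts_rep%d", seq_len(config@n_replicates)),
                         "counts_pdna"))

  # per-gene fitness (per doubling); controls contribute 0, essential
  # pseudo-genes the essential value
  genes <- .simGeneNames(config@n_genes)
  set.seed(seeds[["fitness"]])
  n_ess_like <- round(config@fraction_essential * config@n_genes)
  ess_like <- sample(genes, n_ess_like)
  f <- stats::setNames(
    ifelse(genes %in% ess_like, config@fitness_essential, config@fitness_normal) +
      stats::rnorm(length(genes), 0, config@fitness_sd),
    genes
  )
  fo <- config@fitness_override
  if (nrow(fo)) f[fo$gene] <- fo$fitness
  if (config@n_essential > 0L) {
    f <- c(f, stats::setNames(rep(config@fitness_essential, config@n_essential),
                              sprintf("ESS%d", seq_len(config@n_essential))))
  }

  # guide cutting efficiency on [0, 1]
  g <- guides(lib)
  set.seed(seeds[["efficiency"]])
  a <- config@efficiency_mean * config@efficiency_shape
  b <- (1 - config@efficiency_mean) * config@efficiency_shape
  e <- stats::setNames(
    if (config@efficiency_mean >= 1) rep(1, nrow(g)) else stats::rbeta(nrow(g), a, b),
    g$guide_id
  )

  # true per-construct growth (per doubling, log2 units)
  fit_of <- function(gene) ifelse(is.na(gene), 0, unname(f[gene]))
  # essential controls carry their pseudo-gene's fitness through sp_gene/sa_gene
  e_sp <- unname(e[k$sp_guide_id]); e_sa <- unname(e[k$sa_guide_id])
  both_targeting <- k$sp_category == "targeting" & k$sa_category == "targeting"
  eps <- .epsilonFor(k$sp_gene, k$sa_gene, config@interactions)
  eps[!both_targeting] <- 0
  growth <- e_sp * fit_of(k$sp_gene) + e_sa * fit_of(k$sa_gene) + e_sp * e_sa * eps

  # pDNA representation and endpoint composition
  set.seed(seeds[["pdna"]])
  p <- stats::rlnorm(n_con, 0, config@pdna_sigma)
  p <- p / sum(p)
  growth_factor <- 2^(growth * config@doublings)
  w <- p * growth_factor
  w <- w / sum(w)
  expected_lfc <- log2(w / p)

  depth <- round(config@coverage * n_con)
  draw <- function(prob, seed) {
    set.seed(seed)
    if (config@count_model == "multinomial") {
      as.integer(stats::rmultinom(1L, depth, prob))
    } else if (config@dispersion > 0) {
      as.integer(stats::rnbinom(n_con, mu = depth * prob, size = 1 / config@dispersion))
    } else {
      as.integer(stats::rpois(n_con, depth * prob))
    }
  }
  cols <- list(pDNA = draw(p, seeds[["counts_pdna"]]))
  for (r in seq_len(config@n_replicates)) {
    cols[[sprintf("screen_rep%d", r)]] <- draw(w, seeds[[sprintf("counts_rep%d", r)]])
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- k$construct_id
  samples <- data.frame(
    sample_id = colnames(counts),
    condition = c("pDNA", rep("screen", config@n_replicates)),
    replicate = c(1L, seq_len(config@n_replicates)),
    timepoint_days = c(0, rep(config@doublings, config@n_replicates)),
    is_reference = c(TRUE, rep(FALSE, config@n_replicates)),
    stringsAsFactors = FALSE
  )
  truth <- new("SimTruth",
               guide_efficiency = e, gene_fitness = f,
               interactions = config@interactions,
               constructs = data.frame(construct_id = k$construct_id,
                                       pdna_fraction = p, growth = growth,
                                       expected_lfc = expected_lfc,
                                       stringsAsFactors = FALSE),
               doublings = config@doublings)
  list(library = lib, catalog = catalog,
       counts = screenCounts(counts, catalog, samples), truth = truth)
}

#' Noiseless expected-LFC oracle
#'
#' Closed-form expected log2 fold change per construct — the infinite-depth,
#' zero-dispersion limit of \code{\link{simulateScreen}} counts:
#' \code{g_c * T - log2(sum_c p_c * 2^(g_c * T))}. Renormalization is
#' included because a pooled screen measures composition, not absolute
#' growth. Serves as the independent oracle for pipeline tests.
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param catalog the matching \linkS4class{ConstructCatalog}.
#' @return A \code{SummarizedExperiment} with assay \code{"lfc"} (one
#'   column, condition \code{"screen"}).
#' @export
expectedLfcOracle <- function(truth, catalog) {
  tc <- truth@constructs
  p <- tc$pdna_fraction
  gf <- 2^(tc$growth * truth@doublings)
  lfc <- tc$growth * truth@doublings - log2(sum(p * gf))
  m <- matrix(lfc, ncol = 1L,
              dimnames = list(tc$construct_id, "screen"))
  k <- constructs(catalog)
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(lfc = m[k$construct_id, , drop = FALSE]),
    rowData = S4Vectors::DataFrame(k, row.names = k$construct_id),
    colData = S4Vectors::DataFrame(sample_id = "screen", condition = "screen",
                                   n_replicates = 1L, row.names = "screen")
  )
  S4Vectors::metadata(out) <- list(pseudocount = NA_real_,
                                   reference_samples = "expected")
  out
}

#' Recovery metrics against simulation ground truth
#'
#' Fraction of injected negative-interaction pairs called at the z
#' threshold (power), fraction of non-injected distinct-gene pairs called
#' (false-positive rate) and the Spearman rank agreement between injected
#' epsilon and \code{z_gene} over all scored distinct-gene pairs.
#'
#' @param scores gene-pair score table from \code{\link{scoreGenePairs}}.
#' @param truth the matching \linkS4class{SimTruth}.
#' @param z_cut synergy threshold (default -4).
#' @return list(power, fpr, rank_agreement, n_injected, n_null); power is
#'   NA (with a warning) when no negative interactions were injected.
#' @export
evaluateRecovery <- function(scores, truth, z_cut = -4) {
  s <- scores[!scores$same_gene, , drop = FALSE]
  s$epsilon <- .epsilonFor(s$gene_i, s$gene_j, truth@interactions)
  injected <- s$epsilon < 0
  if (!any(injected)) {
    csWarn("no injected negative interactions; power undefined")
    power <- NA_real_
  } else {
    power <- mean(s$z_gene[injected] < z_cut)
  }
  null <- s$epsilon == 0
  list(
    power = power,
    fpr = if (any(null)) mean(s$z_gene[null] < z_cut) else NA_real_,
    rank_agreement = if (nrow(s) >= 3L && stats::sd(s$epsilon) > 0) {
      stats::cor(s$epsilon, s$z_gene, method = "spearman")
    } else NA_real_,
    n_injected = sum(injected), n_null = sum(null)
  )
}

#' Write simulation ground truth TSVs
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param dir output directory; writes \code{truth_constructs.tsv},
#'   \code{truth_guides.tsv}, \code{truth_genes.tsv},
#'   \code{truth_interactions.tsv}.
#' @return The directory, invisibly.
#' @export
writeSimTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTsv(truth@constructs, file.path(dir, "truth_constructs.tsv"))
  .writeTsv(data.frame(guide_id = names(truth@guide_efficiency),
                       efficiency = unname(truth@guide_efficiency),
                       stringsAsFactors = FALSE),
            file.path(dir, "truth_guides.tsv"))
  .writeTsv(data.frame(gene = names(truth@gene_fitness),
                       fitness = unname(truth@gene_fitness),
                       stringsAsFactors = FALSE),
            file.path(dir, "truth_genes.tsv"))
  .writeTsv(truth@interactions, file.path(dir, "truth_interactions.tsv"))
  invisible(dir)
}
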