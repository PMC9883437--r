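#' @import methods
NULL

.ORTHOLOGS <- c("SpCas9", "SaCas9")
.CATEGORIES <- c("targeting", "non_targeting", "essential_control", "safe_harbor")
.PAIR_CLASSES <- c("gene_gene", "same_gene", "gene_control", "control_control")

#' Dual-ortholog guide library
#'
#' Holds the sgRNA annotation for a dual-Cas9 combinatorial library: each
#' guide directs either S. pyogenes or S. aureus Cas9 and is a targeting
#' guide (with a target gene), a non-targeting control, an essential-gene
#' control, or a safe-harbor control.
#'
#' @slot guides data.frame with columns \code{guide_id}, \code{ortholog},
#'   \code{category}, \code{target_gene}, \code{note}.
#' @exportClass GuideLibrary
setClass("GuideLibrary", slots = c(guides = "data.frame"))

setValidity("GuideLibrary", function(object) {
  g <- object@guides
  req <- c("guide_id", "ortholog", "category", "target_gene", "note")
  if (!all(req %in% names(g))) {
    return(sprintf("missing column(s): %s", paste(setdiff(req, names(g)), collapse = ", ")))
  }
  if (anyDuplicated(g$guide_id)) {
    dup <- unique(g$guide_id[duplicated(g$guide_id)])
    return(sprintf("duplicate guide_id: %s", paste(dup, collapse = ", ")))
  }
  if (!all(g$ortholog %in% .ORTHOLOGS)) {
    return(sprintf("unknown ortholog token(s): %s",
                   paste(unique(setdiff(g$ortholog, .ORTHOLOGS)), collapse = ", ")))
  }
  if (!all(g$category %in% .CATEGORIES)) {
    return(sprintf("unknown category token(s): %s",
                   paste(unique(setdiff(g$category, .CATEGORIES)), collapse = ", ")))
  }
  bad <- g$category == "targeting" & (is.na(g$target_gene) | g$target_gene == "")
  if (any(bad)) {
    return(sprintf("targeting guide(s) without target_gene: %s",
                   paste(g$guide_id[bad], collapse = ", ")))
  }
  bad <- g$category == "non_targeting" & !is.na(g$target_gene)
  if (any(bad)) {
    return(sprintf("non_targeting guide(s) with a target_gene: %s",
                   paste(g$guide_id[bad], collapse = ", ")))
  }
  if (!all(.ORTHOLOGS %in% g$ortholog)) {
    return("library must contain at least one guide of each Cas9 ortholog")
  }
  TRUE
})

#' Catalog of dual-guide constructs
#'
#' One row per lentiviral construct, i.e. per ordered (SpCas9 guide, SaCas9
#' guide) pair, annotated with the guides' categories, target genes and the
#' derived pair class (\code{gene_gene}, \code{same_gene}, \code{gene_control},
#' \code{control_control}).
#'
#' @slot constructs data.frame with columns \code{construct_id},
#'   \code{sp_guide_id}, \code{sa_guide_id}, \code{sp_category},
#'   \code{sa_category}, \code{sp_gene}, \code{sa_gene}, \code{pair_class},
#'   \code{gene_i}, \code{gene_j} (unordered gene pair, NA for control sides).
#' @exportClass ConstructCatalog
setClass("ConstructCatalog", slots = c(constructs = "data.frame"))

setValidity("ConstructCatalog", function(object) {
  k <- object@constructs
  req <- c("construct_id", "sp_guide_id", "sa_guide_id", "sp_category",
           "sa_category", "sp_gene", "sa_gene", "pair_class", "gene_i", "gene_j")
  if (!all(req %in% names(k))) {
    return(sprintf("missing column(s): %s", paste(setdiff(req, names(k)), collapse = ", ")))
  }
  if (anyDuplicated(k$construct_id)) return("duplicate construct_id")
  if (anyDuplicated(paste(k$sp_guide_id, k$sa_guide_id, sep = ";"))) {
    return("duplicate (sp_guide_id, sa_guide_id) pair")
  }
  if (!all(k$pair_class %in% .PAIR_CLASSES)) return("invalid pair_class value")
  TRUE
})

#' @describeIn GuideLibrary Construct a validated library from a guide
#'   annotation data.frame (missing \code{target_gene}/\code{note} columns are
#'   added as NA).
#' @param guides data.frame of guide annotations.
#' @export
GuideLibrary <- function(guides) {
  guides <- as.data.frame(guides, stringsAsFactors = FALSE)
  if (!"target_gene" %in% names(guides)) guides$target_gene <- NA_character_
  if (!"note" %in% names(guides)) guides$note <- NA_character_
  guides$target_gene[!is.na(guides$target_gene) & guides$target_gene == ""] <- NA_character_
  rownames(guides) <- NULL
  new("GuideLibrary", guides = guides)
}

#' Configuration of a simulated dual-guide screen
#'
#' Generative parameters for a pooled dual-Cas9 knockout screen: library
#' composition, per-gene per-doubling fitness, injected pairwise interactions,
#' guide cutting efficiency, plasmid-pool representation spread, growth
#' duration in population doublings, sequencing coverage and count
#' overdispersion. Defaults emulate the screened study conditions: 2 guides
#' per gene per ortholog (4 per gene overall), 14 non-targeting guides per
#' ortholog, 21 doublings (a 21-day screen at 24 h doubling time), coverage of
#' 1000 reads per construct, and duplicate endpoint replicates.
#'
#' @slot n_genes number of targeted genes.
#' @slot guides_per_gene guides per gene per ortholog.
#' @slot n_nt non-targeting guides per ortholog.
#' @slot n_essential essential-control guides per ortholog.
#' @slot fraction_essential fraction of target genes drawn as essential-like.
#' @slot fitness_essential per-doubling fitness of essential-like genes.
#' @slot fitness_normal per-doubling fitness of the remaining genes.
#' @slot fitness_sd per-gene fitness jitter (per doubling).
#' @slot fitness_override data.frame(gene, fitness): explicit per-doubling
#'   fitness values applied after the random draw (e.g. to plant
#'   fitness-positive genes for compensation scenarios).
#' @slot interactions data.frame(gene_i, gene_j, epsilon): per-doubling
#'   interaction terms for distinct targeting gene pairs.
#' @slot efficiency_mean,efficiency_shape mean and concentration of the Beta
#'   distribution of guide cutting efficiency on \code{[0, 1]}.
#' @slot pdna_sigma sdlog of the lognormal pDNA representation.
#' @slot doublings number of population doublings (T).
#' @slot coverage reads per construct per sample.
#' @slot dispersion negative-binomial dispersion of read counts (0 = Poisson).
#' @slot count_model "nb" or "multinomial" (exact per-sample depth).
#' @slot n_replicates endpoint replicates.
#' @slot seed master seed; all streams derive from it.
#' @exportClass SimConfig
setClass("SimConfig", slots = c(
  n_genes = "integer", guides_per_gene = "integer", n_nt = "integer",
  n_essential = "integer", fraction_essential = "numeric",
  fitness_essential = "numeric", fitness_normal = "numeric",
  fitness_sd = "numeric", fitness_override = "data.frame",
  interactions = "data.frame",
  efficiency_mean = "numeric", efficiency_shape = "numeric",
  pdna_sigma = "numeric", doublings = "numeric", coverage = "numeric",
  dispersion = "numeric", count_model = "character",
  n_replicates = "integer", seed = "integer"
))

setValidity("SimConfig", function(object) {
  if (object@n_genes < 1L) return("n_genes must be >= 1")
  if (object@guides_per_gene < 1L) return("guides_per_gene must be >= 1")
  if (object@n_nt < 0L || object@n_essential < 0L) return("control counts must be >= 0")
  if (object@coverage <= 0) return("coverage must be positive")
  if (object@doublings <= 0) return("doublings must be positive")
  if (object@dispersion < 0) return("dispersion must be >= 0")
  if (object@efficiency_mean <= 0 || object@efficiency_mean > 1) {
    return("efficiency_mean must be in (0, 1]")
  }
  if (!object@count_model %in% c("nb", "multinomial")) {
    return("count_model must be 'nb' or 'multinomial'")
  }
  if (object@n_replicates < 1L) return("n_replicates must be >= 1")
  fo <- object@fitness_override
  if (nrow(fo) && !all(c("gene", "fitness") %in% names(fo))) {
    return("fitness_override needs columns gene, fitness")
  }
  ia <- object@interactions
  if (nrow(ia)) {
    if (!all(c("gene_i", "gene_j", "epsilon") %in% names(ia))) {
      return("interactions needs columns gene_i, gene_j, epsilon")
    }
    if (any(ia$gene_i == ia$gene_j)) {
      return("interaction terms are defined only for distinct genes")
    }
  }
  TRUE
})

#' Ground truth of a simulated screen
#'
#' @slot guide_efficiency named numeric, cutting efficiency per guide.
#' @slot gene_fitness named numeric, per-doubling fitness per gene
#'   (controls contribute fitness 0).
#' @slot interactions data.frame(gene_i, gene_j, epsilon).
#' @slot constructs data.frame(construct_id, growth, expected_lfc): true
#'   per-doubling growth g_c and the closed-form expected log2 fold change.
#' @slot doublings numeric, the growth duration used.
#' @exportClass SimTruth
setClass("SimTruth", slots = c(
  guide_efficiency = "numeric", gene_fitness = "numeric",
  interactions = "data.frame", constructs = "data.frame",
  doublings = "numeric"
))
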