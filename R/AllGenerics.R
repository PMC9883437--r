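#' Accessors for screen data classes
#'
#' \code{guides()} returns the guide annotation data.frame of a
#' \linkS4class{GuideLibrary}; \code{constructs()} the construct table of a
#' \linkS4class{ConstructCatalog}; \code{pairClassCounts()} the breakdown of a
#' catalog by pair class.
#'
#' @param x a GuideLibrary or ConstructCatalog.
#' @return A data.frame (or named integer vector for
#'   \code{pairClassCounts()}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("guides", function(x) standardGeneric("guides"))

#' @rdname accessors
#' @export
setGeneric("constructs", function(x) standardGeneric("constructs"))

#' @rdname accessors
#' @export
setGeneric("pairClassCounts", function(x) standardGeneric("pairClassCounts"))

#' @rdname accessors
#' @export
setMethod("guides", "GuideLibrary", function(x) x@guides)

#' @rdname accessors
#' @export
setMethod("constructs", "ConstructCatalog", function(x) x@constructs)

#' @rdname accessors
#' @export
setMethod("pairClassCounts", "ConstructCatalog", function(x) {
  tab <- table(factor(x@constructs$pair_class, levels = .PAIR_CLASSES))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})

#' @rdname accessors
#' @export
setMethod("length", "GuideLibrary", function(x) nrow(x@guides))

#' @rdname accessors
#' @export
setMethod("length", "ConstructCatalog", function(x) nrow(x@constructs))

setMethod("show", "GuideLibrary", function(object) {
  g <- object@guides
  cat(sprintf("GuideLibrary with %d guides\n", nrow(g)))
  for (o in .ORTHOLOGS) {
    sub <- g[g$ortholog == o, , drop = FALSE]
    cat(sprintf("  %s: %d (%s)\n", o, nrow(sub),
                paste(sprintf("%s=%d", names(table(sub$category)),
                              as.integer(table(sub$category))), collapse = ", ")))
  }
  ng <- length(unique(stats::na.omit(g$target_gene[g$category == "targeting"])))
  cat(sprintf("  target genes: %d\n", ng))
})

setMethod("show", "ConstructCatalog", function(object) {
  cat(sprintf("ConstructCatalog with %d constructs\n", nrow(object@constructs)))
  pc <- pairClassCounts(object)
  cat(sprintf("  %s\n", paste(sprintf("%s=%d", names(pc), pc), collapse = ", ")))
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:\n")
  cat(sprintf("  library: %d genes x %d guides/ortholog + %d NT + %d essential controls per ortholog\n",
              object@n_genes, object@guides_per_gene, object@n_nt, object@n_essential))
  cat(sprintf("  growth: %.3g doublings; coverage %.3g reads/construct; dispersion %.3g (%s)\n",
              object@doublings, object@coverage, object@dispersion, object@count_model))
  cat(sprintf("  fitness: %.0f%% essential-like at %.3g/doubling; efficiency Beta(mean %.2f, shape %.3g)\n",
              100 * object@fraction_essential, object@fitness_essential,
              object@efficiency_mean, object@efficiency_shape))
  cat(sprintf("  interactions: %d injected; replicates: %d; seed: %d\n",
              nrow(object@interactions), object@n_replicates, object@seed))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d guides, %d genes, %d injected interactions, %d constructs, T = %.3g doublings\n",
              length(object@guide_efficiency), length(object@gene_fitness),
              nrow(object@interactions), nrow(object@constructs), object@doublings))
})
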