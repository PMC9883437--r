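# The generative screen model and its ground-truth oracle.

test_that("simulation is deterministic given the seed and validates config", {
  cfg <- simConfig(n_genes = 5L, seed = 77)
  a <- simulateScreen(cfg)
  b <- simulateScreen(cfg)
  expect_identical(SummarizedExperiment::assay(a$counts, "counts"),
                   SummarizedExperiment::assay(b$counts, "counts"))
  expect_identical(a$truth@constructs, b$truth@constructs)
  c2 <- simulateScreen(simConfig(n_genes = 5L, seed = 78))
  expect_false(identical(SummarizedExperiment::assay(a$counts),
                         SummarizedExperiment::assay(c2$counts)))
  expect_error(simConfig(coverage = 0), "coverage")
  expect_error(simConfig(doublings = -1), "doublings")
  expect_error(simConfig(interactions = data.frame(gene_i = "G001",
                                                   gene_j = "G001",
                                                   epsilon = -1)), "distinct")
})

test_that("library layout and catalog size follow the configuration", {
  cfg <- simConfig(n_genes = 50L, guides_per_gene = 2L, n_nt = 14L,
                   n_essential = 0L, seed = 1)
  sim <- simulateScreen(cfg)
  # (50 * 2 + 14)^2 = 12,996 constructs
  expect_equal(length(sim$catalog), 12996L)
  g <- guides(sim$library)
  expect_equal(sum(g$ortholog == "SpCas9"), 114L)
  expect_equal(sum(g$category == "non_targeting"), 28L)
})

test_that("multinomial mode conserves the configured depth exactly", {
  cfg <- simConfig(n_genes = 4L, coverage = 200, count_model = "multinomial",
                   seed = 2)
  sim <- simulateScreen(cfg)
  m <- SummarizedExperiment::assay(sim$counts, "counts")
  depth <- round(200 * nrow(m))
  expect_true(all(colSums(m) == depth))
  expect_true(all(m >= 0))
})

test_that("a null high-coverage screen has LFCs pinned near zero", {
  cfg <- simConfig(n_genes = 4L, n_essential = 0L, fraction_essential = 0,
                   fitness_sd = 0, dispersion = 0, coverage = 1e6,
                   pdna_sigma = 0.3, seed = 4)
  sim <- simulateScreen(cfg)
  lfc <- SummarizedExperiment::assay(computeLfc(countsToLog2RPM(sim$counts)))
  expect_lt(max(abs(lfc)), 0.05)
})

test_that("the expected-LFC oracle matches hand renormalization", {
  # two constructs, growth {0, -1}, T = 1, equal pDNA:
  # endpoint shares {2/3, 1/3} vs pDNA {1/2, 1/2}
  lib <- GuideLibrary(data.frame(
    guide_id = c("sp1", "sa1", "sa2"), ortholog = c("SpCas9", "SaCas9", "SaCas9"),
    category = c("targeting", "non_targeting", "non_targeting"),
    target_gene = c("A", NA, NA), stringsAsFactors = FALSE
  ))
  cat2 <- buildAllByAllCatalog(lib)
  truth <- new("SimTruth",
               guide_efficiency = c(sp1 = 1, sa1 = 1, sa2 = 1),
               gene_fitness = c(A = 0),
               interactions = data.frame(gene_i = character(),
                                         gene_j = character(),
                                         epsilon = numeric()),
               constructs = data.frame(
                 construct_id = constructs(cat2)$construct_id,
                 pdna_fraction = c(0.5, 0.5), growth = c(0, -1),
                 expected_lfc = NA_real_, stringsAsFactors = FALSE),
               doublings = 1)
  lfc <- SummarizedExperiment::assay(expectedLfcOracle(truth, cat2))
  expect_equal(unname(lfc[, 1]), c(log2(2 / 1.5), log2(1 / 1.5)), tolerance = 1e-12)
  # uniform growth cancels after renormalization
  truth@constructs$growth <- c(-2, -2)
  lfc0 <- SummarizedExperiment::assay(expectedLfcOracle(truth, cat2))
  expect_equal(unname(lfc0[, 1]), c(0, 0))
})

test_that("the oracle is the high-depth low-noise limit of simulated counts", {
  # mild fitness spread keeps every construct deep enough that count noise
  # stays well inside the comparison band
  cfg <- simConfig(n_genes = 5L, n_essential = 0L, fraction_essential = 0,
                   coverage = 1e7, dispersion = 0, n_replicates = 2L, seed = 8)
  sim <- simulateScreen(cfg)
  # tiny pseudocount so the comparison is not floored at depleted constructs
  obs <- SummarizedExperiment::assay(averageReplicates(
    computeLfc(countsToLog2RPM(sim$counts, pseudocount = 1e-4))))
  exp_lfc <- SummarizedExperiment::assay(expectedLfcOracle(sim$truth, sim$catalog))
  expect_lt(max(abs(obs[, "screen"] - exp_lfc[rownames(obs), "screen"])), 0.02)
})

test_that("injected interactions scale with efficiency and both guides cutting", {
  # epsilon only acts through e_sp * e_sa: with efficiencies fixed at 1 the
  # pair's constructs sit exactly epsilon * T below the additive expectation
  cfg <- simConfig(n_genes = 3L, n_essential = 0L, fraction_essential = 0,
                   fitness_sd = 0, efficiency_mean = 1, doublings = 2,
                   interactions = data.frame(gene_i = "G001", gene_j = "G002",
                                             epsilon = -3),
                   seed = 10)
  sim <- simulateScreen(cfg)
  k <- constructs(sim$catalog)
  tc <- sim$truth@constructs
  pair <- k$pair_class %in% c("gene_gene") &
    pmin(k$sp_gene, k$sa_gene) == "G001" & pmax(k$sp_gene, k$sa_gene) == "G002"
  expect_equal(unique(tc$growth[pair]), -3)
  expect_equal(unique(tc$growth[!pair]), 0)
  # before renormalization: deficit of epsilon * T log2 units
  expect_equal(unique(tc$growth[pair] * sim$truth@doublings), -6)
})

test_that("recovery metrics behave on oracle, null and shuffled scores", {
  cfg <- simConfig(n_genes = 8L, n_essential = 0L, seed = 6,
                   interactions = data.frame(gene_i = "G002", gene_j = "G005",
                                             epsilon = -0.05))
  sim <- simulateScreen(cfg)
  lfc <- expectedLfcOracle(sim$truth, sim$catalog)
  scores <- scoreGenePairs(fitAnchorModels(lfc, computeBaseLfc(lfc)))
  rec <- evaluateRecovery(scores, sim$truth)
  expect_equal(rec$power, 1)
  expect_equal(rec$fpr, 0)
  expect_equal(rec$n_injected, 1L)
  # no injected interactions: power undefined but FPR still computed
  cfg0 <- simConfig(n_genes = 8L, n_essential = 0L, seed = 6)
  sim0 <- simulateScreen(cfg0)
  lfc0 <- expectedLfcOracle(sim0$truth, sim0$catalog)
  scores0 <- scoreGenePairs(fitAnchorModels(lfc0, computeBaseLfc(lfc0)))
  expect_warning(rec0 <- evaluateRecovery(scores0, sim0$truth), "power undefined")
  expect_true(is.na(rec0$power))
  expect_equal(rec0$fpr, 0)
})

test_that("strengthening an interaction never raises its pair score", {
  mean_z <- function(eps) {
    zs <- vapply(1:20, function(s) {
      cfg <- simConfig(n_genes = 10L, seed = 1000 + s,
                       interactions = data.frame(gene_i = "G003",
                                                 gene_j = "G008",
                                                 epsilon = eps))
      sc <- scoreScreen(simulateScreen(cfg)$counts)
      sc$z_gene[sc$gene_i == "G003" & sc$gene_j == "G008"]
    }, numeric(1L))
    mean(zs)
  }
  z_weak <- mean_z(-0.02)
  z_strong <- mean_z(-0.06)
  expect_lte(z_strong, z_weak)
})
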