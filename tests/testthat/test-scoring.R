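# Anchor-regression interaction scoring: base LFCs, OLS fits, residual
# z-scores and gene-pair aggregation.

test_that("base LFC is the mean over control pairings", {
  # one targeting guide against 14 non-targeting partners, all LFC -1
  lib <- simpleLibrary(genes = "A", guides_per_gene = 1L, n_nt = 14L)
  cat_a <- buildAllByAllCatalog(lib)
  k <- constructs(cat_a)
  m <- lfcMatrix(cat_a, "c1", fill = 0.25)
  m[k$sp_guide_id == "sp_A_1" & k$sa_category == "non_targeting", 1] <- -1
  base <- computeBaseLfc(lfcSE(m, cat_a))
  row <- base[base$guide_id == "sp_A_1", ]
  expect_equal(row$base_lfc, -1)
  expect_equal(row$n_control_partners, 14L)

  # {0.5, 1.5, 1.0} -> 1.0
  lib3 <- simpleLibrary(genes = "A", guides_per_gene = 1L, n_nt = 3L)
  cat3 <- buildAllByAllCatalog(lib3)
  k3 <- constructs(cat3)
  m3 <- lfcMatrix(cat3, "c1")
  m3[k3$sp_guide_id == "sp_A_1" & k3$sa_category == "non_targeting", 1] <- c(0.5, 1.5, 1.0)
  b3 <- computeBaseLfc(lfcSE(m3, cat3))
  expect_equal(b3$base_lfc[b3$guide_id == "sp_A_1"], 1.0)
})

test_that("guides without control pairings are omitted with a warning", {
  # Sa side has no non-targeting guides, so Sa guides get no base LFC
  g <- rbind(
    data.frame(guide_id = "sp_A_1", ortholog = "SpCas9", category = "targeting",
               target_gene = "A", stringsAsFactors = FALSE),
    data.frame(guide_id = c("sa_A_1", "sa_nt1", "sa_nt2"), ortholog = "SaCas9",
               category = c("targeting", "non_targeting", "non_targeting"),
               target_gene = c("A", NA, NA), stringsAsFactors = FALSE)
  )
  lib <- GuideLibrary(g)
  cat_m <- buildAllByAllCatalog(lib)
  m <- lfcMatrix(cat_m, "c1", fill = -0.5)
  expect_warning(base <- computeBaseLfc(lfcSE(m, cat_m)), "no control pairing")
  expect_true("sp_A_1" %in% base$guide_id)
  expect_false("sa_A_1" %in% base$guide_id)
  expect_true("sa_A_1" %in% attr(base, "omitted"))
  # a catalog with no control guides at all cannot produce base LFCs
  lib0 <- simpleLibrary(genes = "A", guides_per_gene = 1L, n_nt = 0L)
  cat0 <- buildAllByAllCatalog(lib0)
  expect_error(computeBaseLfc(lfcSE(lfcMatrix(cat0, "c1"), cat0)),
               class = "config_error")
})

test_that("single-anchor OLS matches hand arithmetic and guards degeneracy", {
  # collinear points
  fit <- fitAnchorModel(c(0, 1, 2), c(1, 3, 5))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$residuals, c(0, 0, 0))
  # closed form by hand: m = cov/var = 1.5, b = -0.5
  fit2 <- fitAnchorModel(c(0, 1, 2), c(0, 0, 3))
  expect_equal(fit2$slope, 1.5)
  expect_equal(fit2$intercept, -0.5)
  expect_equal(fit2$residuals, c(0.5, -1.0, 0.5))
  expect_equal(fit2$residual_mean, 0)
  # zero-variance regressor
  expect_error(fitAnchorModel(c(1, 1, 1), c(0, 1, 2)),
               class = "degenerate_fit_error")
  expect_error(fitAnchorModel(1, 2), class = "degenerate_fit_error")
})

test_that("anchor OLS agrees with lm on random fits", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(3:12, 1L)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    fit <- fitAnchorModel(x, y)
    ref <- unname(coef(lm(y ~ x)))
    expect_equal(fit$intercept, ref[1], tolerance = 1e-9)
    expect_equal(fit$slope, ref[2], tolerance = 1e-9)
    expect_equal(fit$residuals, unname(resid(lm(y ~ x))), tolerance = 1e-9)
  }
})

test_that("residual z-scores use the sample sd and guard zero spread", {
  z <- zscoreResiduals(c(0.5, -1.0, 0.5))
  expect_equal(z, c(0.5, -1.0, 0.5) / sqrt(0.75), ignore_attr = TRUE)
  expect_equal(zscoreResiduals(c(-1, 1)), c(-1, 1) / sqrt(2), ignore_attr = TRUE)
  zc <- zscoreResiduals(c(0.3, 0.3, 0.3))
  expect_equal(as.numeric(zc), c(0, 0, 0))
  expect_true(attr(zc, "degenerate"))
  expect_error(zscoreResiduals(0.5), class = "degenerate_fit_error")
  # mean 0 / sd 1 whenever not degenerate
  set.seed(21)
  for (i in 1:25) {
    z <- zscoreResiduals(rnorm(sample(2:30, 1L)))
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sd(z) - 1), 1e-9)
  }
})

# hand-built residual-z table: 8 constructs of a pair, both orientations
.pairZTable <- function(gene_a = "I", gene_b = "J", z = -2, n_con = 8L) {
  con <- sprintf("c%d", seq_len(n_con))
  data.frame(
    condition = "c1",
    anchor_gene = rep(c(gene_a, gene_b), each = n_con),
    partner_gene = rep(c(gene_b, gene_a), each = n_con),
    anchor_guide = paste0("g", rep(c(gene_a, gene_b), each = n_con)),
    partner_guide = paste0("g", rep(c(gene_b, gene_a), each = n_con)),
    construct_id = rep(con, 2L),
    y = -1.5, x = 0, z = z,
    stringsAsFactors = FALSE
  )
}

test_that("gene-pair aggregation matches hand arithmetic and is symmetric", {
  sc <- scoreGenePairs(.pairZTable())
  expect_equal(sc$n_constructs, 8L)
  expect_equal(sc$s_i, -16 / sqrt(8))
  expect_equal(sc$s_j, -16 / sqrt(8))
  expect_equal(sc$z_gene, -8)
  expect_equal(sc$mean_observed_lfc, -1.5)
  # all-zero z table scores zero
  expect_equal(scoreGenePairs(.pairZTable(z = 0))$z_gene, 0)
  # exchanging gene labels leaves the score identical
  swapped <- scoreGenePairs(.pairZTable(gene_a = "J", gene_b = "I"))
  expect_equal(swapped$z_gene, sc$z_gene)
  expect_equal(swapped$gene_i, sc$gene_i)
  # single-orientation pair is flagged asymmetric
  half <- .pairZTable()[1:8, ]
  expect_warning(sc_half <- scoreGenePairs(half), "orientation")
  expect_true(sc_half$asymmetric)
})

test_that("batched anchor fitting matches the single-anchor path", {
  cfg <- simConfig(n_genes = 6L, n_essential = 0L, seed = 33)
  sim <- simulateScreen(cfg)
  lfc <- averageReplicates(computeLfc(countsToLog2RPM(sim$counts)))
  base <- computeBaseLfc(lfc)
  fits <- fitAnchorModels(lfc, base, min_points = 2L)
  # reference path: per-anchor closed-form fit + z-scoring
  for (a in sample(unique(fits$z$anchor_guide), 4L)) {
    rows <- fits$z[fits$z$anchor_guide == a, ]
    ref <- fitAnchorModel(rows$x, rows$y)
    frow <- fits$fits[fits$fits$anchor_guide == a, ]
    expect_equal(frow$slope, ref$slope, tolerance = 1e-10)
    expect_equal(frow$intercept, ref$intercept, tolerance = 1e-10)
    expect_equal(rows$z, as.numeric(zscoreResiduals(ref$residuals)),
                 tolerance = 1e-10)
  }
  # within-anchor z residuals are standardized
  for (a in unique(fits$z$anchor_guide)[1:5]) {
    zz <- fits$z$z[fits$z$anchor_guide == a]
    expect_lt(abs(mean(zz)), 1e-9)
    expect_lt(abs(sd(zz) - 1), 1e-9)
  }
  # anchors below min_points are excluded, not fit: dropping one Sa guide's
  # base LFC leaves every Sp anchor with 11 partners (Sa anchors keep 12)
  base2 <- base[base$guide_id != "sa_G001_1", ]
  expect_warning(fits12 <- fitAnchorModels(lfc, base2, min_points = 12L),
                 "excluded")
  expect_true(all(grepl("^sa_", fits12$fits$anchor_guide)))
  expect_true(all(fits12$excluded$reason == "too_few_partners"))
  expect_true(all(grepl("^sp_", fits12$excluded$anchor_guide)))
})

test_that("noiseless null screens score exactly zero everywhere", {
  # fitness varies across genes (so the regressor is informative) but the
  # expected-LFC oracle removes all measurement noise
  cfg <- simConfig(n_genes = 8L, n_essential = 0L, seed = 5)
  sim <- simulateScreen(cfg)
  lfc <- expectedLfcOracle(sim$truth, sim$catalog)
  base <- computeBaseLfc(lfc)
  fits <- fitAnchorModels(lfc, base)
  scores <- scoreGenePairs(fits)
  expect_true(all(abs(scores$z_gene) < 1e-6))
})

test_that("a single injected interaction is the minimum noiseless score", {
  cfg <- simConfig(n_genes = 8L, n_essential = 0L, seed = 6,
                   interactions = data.frame(gene_i = "G002", gene_j = "G005",
                                             epsilon = -0.05))
  sim <- simulateScreen(cfg)
  lfc <- expectedLfcOracle(sim$truth, sim$catalog)
  scores <- scoreGenePairs(fitAnchorModels(lfc, computeBaseLfc(lfc)))
  scores <- scores[!scores$same_gene, ]
  best <- scores[which.min(scores$z_gene), ]
  expect_equal(c(best$gene_i, best$gene_j), c("G002", "G005"))
})

test_that("end-to-end scoring is deterministic and composes with averaging", {
  sim <- simulateScreen(simConfig(n_genes = 6L, seed = 12))
  s1 <- scoreScreen(sim$counts)
  s2 <- scoreScreen(sim$counts)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # scoring a pre-averaged LFC table gives the same result
  lfc_avg <- averageReplicates(computeLfc(countsToLog2RPM(sim$counts)))
  base <- computeBaseLfc(lfc_avg)
  manual <- scoreGenePairs(fitAnchorModels(lfc_avg, base))
  expect_equal(as.data.frame(s1), as.data.frame(manual), ignore_attr = TRUE)
})

test_that("null orientation scores are standard normal and z_gene is centered", {
  sim <- simulateScreen(simConfig(n_genes = 100L, seed = 3))
  s <- scoreScreen(sim$counts)
  s <- s[!s$same_gene, ]
  expect_lt(abs(mean(s$z_gene)), 0.05)
  # each orientation score is a calibrated N(0, 1) statistic
  ks <- suppressWarnings(ks.test(s$s_i, "pnorm"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_lt(abs(sd(s$s_i) - 1), 0.15)
})
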