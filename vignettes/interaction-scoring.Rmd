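---
title: "Scoring genetic interactions in dual-Cas9 combinatorial knockout screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in dual-Cas9 combinatorial knockout screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscreen)
```

## The measurement and the question

A dual-Cas9 combinatorial screen delivers two guides per lentiviral
construct — one directing *S. pyogenes* Cas9, one directing *S. aureus*
Cas9 — so a pooled library crossing every Sp guide with every Sa guide
knocks out gene pairs at scale. Sequencing the pool at the screen endpoint
and comparing construct abundances against the plasmid DNA (pDNA) used to
make the library yields one log2 fold change (LFC) per construct: the
fitness consequence of the double perturbation. The analysis question is
whether a pair's fitness deviates from what the two single knockouts
predict — more depleted than expected (synergy, synthetic lethality) or
less (buffering, compensation).

## From counts to LFCs

Counts are normalized per sample to log2 reads-per-million with a
pseudocount of 1 RPM (`countsToLog2RPM()`), which keeps zero counts finite
and makes values invariant to sequencing depth. The data do not determine
the normalization uniquely; 1 RPM is the prevailing pooled-screen
convention and the zero-count floor it implies (LFC bounded by
−log2(RPM~ref~ + 1)) should be kept in mind for strongly depleted
constructs. LFC is the sample's log2 RPM minus the reference's; multiple
pDNA samples are averaged on the log2 RPM scale rather than summed as
counts, so each reference carries equal weight regardless of depth.
Whether the reference should be pDNA or an early cellular timepoint is a
design choice the data cannot settle; the sample sheet's `is_reference`
column makes it explicit. Replicates are averaged at the LFC level before
scoring (`averageReplicates()`), matching how duplicate screens are
usually presented; per-replicate scoring remains available by setting
`average_replicates = FALSE` in `scoreScreen()` for QC.

## The anchor-regression interaction model

For every guide $j$, its *base LFC* $x_j$ is the mean LFC of the
constructs pairing it with opposite-ortholog non-targeting controls — an
estimate of its single-knockout phenotype. Safe-harbor guides are not
counted as negative controls by default (`control_categories`), since
cutting controls have their own mild fitness cost.

Each guide then serves as an *anchor*: its combinations with other
targeting guides are regressed on the partners' base LFCs,
$\hat{y}_{ij} = m_i x_j + b_i$ (ordinary least squares, closed form).
The fitted line is the no-interaction expectation: it absorbs the
anchor's own effect (intercept) and any multiplicative scaling of partner
effects in the anchor's background (slope). Residuals $y_{ij} -
\hat{y}_{ij}$ are z-scored within the anchor using the sample (n − 1)
standard deviation. Anchors with fewer than `min_points = 10` usable
partners are dropped rather than fit — a line through a handful of points
is not an expectation worth standardizing against — and a zero-variance
regressor (all partners with identical base LFC) is treated as degenerate.
When residual spread falls below `sd_tol = 1e-8` (e.g. noiseless synthetic
data with no interactions) all z-scores of that anchor are set to 0 and
the anchor flagged, rather than dividing by a numerical zero. Same-gene
pairs (both guides targeting one gene) are scored but flagged and excluded
from hit calling by default; constructs whose partner lacks a base LFC are
excluded from the fit and from the pair's construct count, since the
regressor is undefined there.

Gene-pair aggregation fixes one gene as the anchor gene, sums the
z-scored residuals of the pair's $n$ constructs and divides by $\sqrt{n}$;
the calculation is repeated with the other gene anchored and the two
orientation scores combined as $z_{\text{gene}} = (S_I + S_J)/\sqrt{2}$.
The score is exactly symmetric in gene order, and with 2 guides per gene
per ortholog a pair is covered by $n = 8$ constructs.

### Null behaviour of the two-orientation score

Each orientation score is well calibrated: on interaction-free simulated
screens $S_I$ is standard normal to within sampling error (the acceptance
script reports its Kolmogorov–Smirnov statistic). The combined score is
not: both orientations reuse the same construct measurements — a
construct's single LFC contributes one residual to each of its two
anchors — so $S_I$ and $S_J$ are strongly positively correlated and the
$\sqrt{2}$ divisor, which assumes independent orientations, under-corrects.
In the limit where construct-level noise dominates,
$\mathrm{sd}(z_{\text{gene}}) \to \sqrt{2}$; the acceptance script
measures this directly (`null_zgene_sd`, `null_zgene_ks_statistic`). This
is a property of the published aggregation formula, not of this
implementation. Practically it means the $z < -4$ threshold is more
permissive than a standard-normal tail suggests (the null exceedance rate
is reported as `null_pct_zgene_below_minus4`), and the normal-tail
p-values fed into Benjamini–Hochberg are conservative in rank but
anti-conservative in scale. Hit lists are threshold-based and unaffected
in ordering; users needing calibrated tail probabilities should divide
$z_{\text{gene}}$ by the null standard deviation their own screen's
control pairs exhibit.

## Hit calling

A pair with $z_{\text{gene}} <$ `z_cut` (default −4) is synergistic.
"Lethal" is defined relative to the screen: the default `lethality_cut`
is the mean of per-pair mean LFCs over distinct-gene pairs in the same
condition — the dotted-line average of a depletion scatter. Compensation
is operationalized as: synergistic z-score, pair LFC at or above the
lethality cut, and both single-knockout LFCs above `positivity_cut`
(default +0.5), capturing pairs where each single loss improves fitness
but the double returns it to baseline without killing.
$z_{\text{gene}} > |z_\text{cut}|$ is buffering; everything else neutral.
Pairs missing a single-KO estimate keep their synergy status and are
flagged rather than silently classified. The FDR machinery (one-sided
normal lower tail + Benjamini–Hochberg per condition) is the minimal
standard choice and is recorded as such in the output metadata; published
FDR thresholds for this assay do not specify a procedure, so q-values are
method-dependent. Per-pair Mann–Whitney tests are exact (full rank-sum
distribution) when both groups have ≤ 8 tie-free observations — the
8-construct pair versus 56 gene-control constructs design uses the
tie-corrected normal approximation — and top hits rank by ascending z,
then ascending mean LFC, then gene pair lexicographically.

## What the simulator emulates — and what it does not

`simulateScreen()` draws pDNA representation from a lognormal
(`pdna_sigma = 0.5` sdlog, a typical cloning-spread), guide cutting
efficiency from a Beta with mean 0.8 and concentration 10, per-gene
per-doubling fitness (20% of genes essential-like at −0.25 per doubling,
the rest near 0 with 0.02 jitter; explicit values can be planted with
`fitness_override`), and pairwise interaction terms $\epsilon_{IJ}$ that
act only through both guides cutting ($e_{sp} e_{sa} \epsilon$ — a
non-cutting guide cannot produce epistasis). Construct growth compounds
over `doublings = 21` (a 21-day screen at 24 h doubling; ≈ 16.8 for a
30 h doubler), endpoint abundance is renormalized — a pooled screen
measures composition, not absolute growth, so uniform fitness cancels —
and reads are drawn negative-binomially at `coverage = 1000` reads per
construct with `dispersion = 0.15`, or multinomially when exact depth is
needed. The dispersion default was calibrated once so that simulated
replicate LFC concordance lands in the Pearson 0.93–0.95 range reported
for well-executed screens of this design; it is a calibrated input, not a
measured property of any particular dataset. All randomness derives from
one seed via named substreams, so identical configurations are
byte-identical.

The simulator deliberately omits PCR jackpotting, recombination between
the two guide cassettes, multiple infection (MOI > 1), cell-cycle and
density effects, and any transcriptional adaptation. Passing recovery
tests therefore demonstrates that the scoring pipeline inverts this
generative model — additive efficiency-weighted fitness plus interaction,
compositional measurement, overdispersed counts — not that it is robust
to every artifact of real screens.

## Numerical choices and problem sizes

Closed-form OLS is used throughout (cross-checked against `lm()` in the
test suite at 10⁻⁹); grouped fits are computed by vectorized grouped sums,
which the tests verify against the single-anchor path. Ties in top-hit
ranking break by mean LFC then gene pair so output order is total and
reproducible; all TSV outputs are written in full precision and the
manifest records configuration and input checksums. The test suite runs
entirely on synthetic data built in code: unit fixtures use 1–10 gene
libraries; the null-calibration check scores a 200-gene screen (19,900
pairs, ~171k constructs); recovery runs 25 seeded 20-gene screens with an
injected $\epsilon = -2$ and 5 compensation scenarios. These sizes were
chosen to exercise the estimator's asymptotics while keeping a full test
run in well under a minute per heavy case on one CPU.

## Known limitations

Counts are assumed already deconvolved; no read-level processing is
offered. The library composition is taken as given — the builder reports
the pair-class breakdown rather than assuming any particular split of
guides into targeting and control sets. Only the anchor-regression
interaction score is implemented; multiplicative (Bliss/Loewe-style)
epistasis models are out of scope. Gene-level ortholog concordance is one
of several defensible constructions (construct-level correlation is
another); it is computed on control-paired base LFCs and labeled as such
in the QC report. And as derived above, the combined gene score is
over-dispersed under the null relative to N(0, 1) — thresholds on it are
empirical, which is precisely how they are used.
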