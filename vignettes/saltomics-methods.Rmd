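---
title: "Methods: salt-tolerance screening and multi-omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salt-tolerance screening and multi-omics integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltomics)
```

# The problem

Breeding salt-tolerant crop varieties starts with a panel screen: dozens of
accessions are grown under control and saline conditions, growth traits are
measured, and the panel is ranked so that extreme tolerant/sensitive pairs can
be carried into physiological and omics follow-up. `saltomics` implements that
evaluation chain and the desk-side statistics of the follow-up: relative
(salt/control) traits, the membership-function composite index, physiological
indicator formulas, relative qPCR expression, threshold screening of
differential genes and metabolites, set overlaps, hypergeometric enrichment,
and FDR-controlled metabolite--gene correlation networks.

# The composite evaluation model

For each accession $i$ and growth trait $j$ (plant height PHt, fresh weight
FW, dry weight DW), replicate measurements are averaged per condition and the
**salt tolerance coefficient** is the ratio of means

$$x_{ij} = \bar{y}_{ij}^{\,\mathrm{salt}} / \bar{y}_{ij}^{\,\mathrm{control}}.$$

The **membership function** rescales each trait across the panel to $[0,1]$:

$$\mu_{ij} = \frac{x_{ij} - \min_i x_{ij}}{\max_i x_{ij} - \min_i x_{ij}},$$

and the **composite evaluation value** is the weighted mean
$D_i = \sum_j w_j \mu_{ij}$ with equal weights $w_j = 1/k$ by default.
Accessions are ranked by $D$ descending; rank 1 is the most tolerant.

Choices worth making explicit:

* **Equal weights.** The published eight-accession worked example is
  reproduced by the unweighted mean: six of its eight $D$ values match at the
  printed 4 decimals, and the other two differ by exactly one unit in the 4th
  decimal — the pattern expected when the upstream $D$ was computed from
  *unrounded* memberships while the table prints memberships rounded to 4
  decimals (each carries up to $5\times10^{-5}$ of rounding error, enough to
  flip the 4th decimal of their mean). The rank order is reproduced exactly.
  Weights remain a user parameter.
* **Ratio of means, not mean of ratios.** Replicates are averaged per
  condition before the quotient, matching how a tolerance index is applied to
  summary values. With balanced replication and multiplicative noise the two
  orders give nearly identical rankings; the choice is recorded because the
  printed tables cannot discriminate between them.
* **Degenerate traits.** If a trait is constant across the panel its
  membership is undefined; all scores are set to 0.5 with a warning, so an
  uninformative trait neither rewards nor penalises anyone.
* **Direction.** All three defaults are growth traits (larger = more
  tolerant); `membership_scores(inverse = TRUE)` supports cost-type traits.
* **Ties** in $D$ are broken by accession id and flagged in the output.
* **Reporting precision** is 4 decimals (via `format_scores()`); full
  precision is kept internally.

The **salt injury index** uses the standard weighted-grade form
$100\sum_g g\,c_g / (G \sum_g c_g)$ on a configurable $0..G$ scale (default
$G=4$); the original grading protocol is citation-only, so this default is an
assumption and is documented as such.

# Physiological formulas

* Relative electrolyte leakage $= 100\,S_1/S_2$ from the pre-/post-boil
  conductivity pair. Values outside $[0,100]$ (possible with noisy exports)
  warn but do not abort.
* Chlorophyll in 95 % ethanol extracts:
  $\mathrm{Chl}\,a = 13.95A_{665} - 6.88A_{649}$,
  $\mathrm{Chl}\,b = 24.96A_{649} - 7.32A_{665}$ (mg/L), total their sum.
  Per-gram fresh weight scaling uses the dilution identity
  $C \times V / m$ with defaults $V = 25$ mL, $m = 0.2$ g. Negative computed
  concentrations are clipped to 0 with a warning. $A_{470}$ is carried but no
  carotenoid equation is applied (none is standard without a carotenoid-
  specific coefficient set).
* Percent change $= 100(t - c)/c$ and the Na$^+$/K$^+$ ratio are plain
  quotients with guarded denominators; time courses are summarised as mean,
  sample SD ($n-1$) and $n$ per (variety, indicator, day) cell.

# qPCR relative expression

The Livak chain: $\Delta Ct = Ct_{\mathrm{target}} - Ct_{\mathrm{reference}}$
per reaction; replicate averaging at the $\Delta Ct$ level within each group;
$\Delta\Delta Ct = \overline{\Delta Ct}_{\mathrm{exp}} -
\overline{\Delta Ct}_{\mathrm{ctl}}$; fold $= 2^{-\Delta\Delta Ct}$. The
negative exponent is the standard convention (sources occasionally print the
positive form by typo); consequently `log2(fold) == -ddct` exactly and
swapping groups inverts the fold. Concordance with RNA-seq is the squared
Pearson correlation of per-gene log2 fold changes over shared genes (>= 3
required).

# Omics threshold screening and enrichment

Boundary semantics follow the printed thresholds literally: significance
requires adjusted $p < 0.05$ (strict) and $|\log_2 FC| \ge 1$ (inclusive),
plus $VIP \ge 1$ (inclusive) for metabolites. Screening is threshold-monotone
and the up/down sets are disjoint by construction. Multi-set overlaps report
all $2^k - 1$ exclusive Venn regions, which sum to the union size.

Enrichment is generic (user-supplied annotation sets and background): for a
set of size $K$ in background $N$ with selection $n$ and overlap $k$, the
upper-tail hypergeometric $p = P(X \ge k)$, adjusted across sets by
Benjamini--Hochberg. `bh_adjust()` is the step-up estimator implemented
directly (sort, multiply by $m/\mathrm{rank}$, enforce monotonicity, cap at
1) so that the test suite can compare it against the naive quadratic
definition as a genuinely independent oracle.

# The co-regulation network

All metabolite $\times$ gene pairs get a Pearson $R$ and a two-sided p-value
from the $t$ statistic with $n-2$ degrees of freedom. The BH family is the
full set of tested pairs. Edges keep pairs with $|R| > 0.8$ and FDR $< 0.05$
(both strict); edge weight is $|R|$, sign follows $R$, and the graph is
bipartite by construction. Centrality is plain degree (connectivity), split
into positive/negative incident edges. Export formats are an edge-list CSV
and GEXF 1.2, both Gephi-ingestible; numbers are serialised at 17 significant
digits so export → import → export round-trips byte-identically.

Two recorded discrepancies: the source protocol states the thresholds both as
($|R|>0.8$, FDR $<0.05$) and, elsewhere, as ($|R|>0.08$, $P<0.01$); the
former is the default and both are parameters. "Edge weight > 0.8" is read as
weight $= |R|$, redundant with the $|R|$ threshold at defaults.

**A power caveat that matters.** With only $n=6$ samples, a pair with true
$\rho = 0.95$ has a typical two-sided $p \approx 0.004$, while BH control at
0.05 across 2500 tested pairs demands raw $p \lesssim 10^{-4}$. So at small
$n$ the FDR conjunct dominates and essentially only near-perfect correlations
survive — the $|R|$ filter alone recovers planted $\rho=0.95$ pairs, the
joint filter does not. This is a property of the statistics, not a bug; users
correlating across few samples should expect very conservative networks (or
relax `fdr_max` consciously). The acceptance suite documents this honestly:
the planted-recovery criterion at $n=6$ fails as specified, while the same
chain at $n=30$ recovers 5/5 planted pairs.

# The synthetic world

The generators emulate the screening study's design, not its biology:

* **Trait trial** (`simulate_trait_trial`): defaults of 63 accessions and 6
  biological replicates mirror the screening design. Each accession draws a
  latent tolerance factor $t_i \sim U(0.1, 1)$ — the fraction of control
  growth retained under salt; control means default to typical pepper
  seedlings (PHt 25 cm, FW 15 g, DW 1.5 g). Measurements are the condition
  expectation times multiplicative log-normal noise (mean 1, relative SD
  `noise_sd`, default 0.05 ~ careful greenhouse phenotyping), keeping traits
  positive at any noise level. Ground truth stores $t_i$ and the implied
  ranking; with zero noise the $D$ ranking recovers it exactly.
* **Feature statistics** (`simulate_feature_stats`): a `de_fraction` of
  features per comparison group receives $\pm$`effect_log2fc`; planted
  adjusted p-values are Beta(0.2, 100) (concentrated near 0) rather than
  derived from a fitted count model — differential-expression model fitting
  is explicitly out of scope, the screen only consumes the statistics table.
  Null features get $N(0, 0.25)$ log2FCs and uniform p. Planted metabolites
  get $VIP = 1 + \mathrm{Exp}(1) \ge 1$, nulls $U(0, 1.2)$.
* **Abundance matrices** (`simulate_abundance_matrices`): background features
  are i.i.d. standard normal across samples (log-scale abundances); each
  planted pair shares a latent factor so its population correlation is
  exactly $\pm$`r_target`. Defaults (6 samples, 5 pairs, $\rho = 0.95$)
  state the network test-bed.

All draws flow through one integer seed via a scoped RNG (`withr::with_seed`),
so identical configurations are byte-identical across runs and platforms, and
the caller's global RNG state is untouched.

What a green test does **not** establish: the generators have no trait
correlations, no genotype-by-replicate structure, no count-based mean-variance
relationship, no compositionality or batch effects, and independent features
outside the planted pairs. They validate the pipeline's arithmetic and
recovery behaviour, not any biological claim.

# Known limitations

* Enrichment background defaults to the union of annotation sets; database-
  backed backgrounds (GO/KEGG) are the caller's responsibility.
* Amplification-efficiency correction and multi-reference normalisation are
  out of scope for the qPCR module (single reference gene assumed).
* Missing abundance values are rejected rather than imputed; drop incomplete
  features upstream.
* ANOVA/post-hoc inference on physiological time courses is delegated to
  standard tools; this package only summarises.
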