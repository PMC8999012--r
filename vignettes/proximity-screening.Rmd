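---
title: "Network proximity screening: model, null, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network proximity screening: model, null, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxscreen)
```

## The model

A drug acts as a local perturbation of the protein–protein interactome. If
its targets sit inside or next to the interactome neighbourhood perturbed by
a disease — the *disease module* — the drug is a plausible (re)purposing
candidate for that disease. proxscreen quantifies this with the network
proximity between a drug module $T$ (the drug's protein targets mapped onto
the interactome) and a disease module $S$ (the disease-associated genes):

$$p_f(T, S) \;=\; \frac{1}{\lVert T \rVert} \sum_{t \in T} \;
  f_{s \in S}\; d(t, s)$$

where $d(t,s)$ is the unweighted shortest-path length and $f$ is one of five
per-target summaries of the distance vector from $t$ to the disease genes:
**minimum** (the classic choice: distance to the nearest disease gene),
**maximum**, **mean**, **median**, and **mode**. The five metrics probe
different geometries: the minimum rewards a single target adjacent to the
module, while the mean/median/maximum ask that the whole target set be
embedded near the whole disease neighbourhood.

Two conventions the formula leaves open are fixed as follows and tested:

* **Mode ties** break toward the *smallest* most-frequent distance. This is
  deterministic and conservative in the direction of proximity.
* **Even-length medians** are the mean of the two central values, so median
  proximities may be half-integers.
* A target that is also a disease gene contributes $d(t,t) = 0$ to every
  summary; zero distances are included, not excluded.
* Targets with no finite distance to any disease gene are dropped from the
  outer mean and counted (`n_targets_dropped`). By default the analysis runs
  on the largest connected component, where this cannot happen; the full
  graph is available via `lcc = FALSE` in `run_pipeline()`.

Proximity is directional: the outer mean always runs over the drug targets,
so $p(T,S) \neq p(S,T)$ in general.

## Significance: degree-preserving randomization

Raw proximity values are incomparable across drugs because hubs are close to
everything. Each observed value is therefore standardized against a null
model: both modules are replaced by random node sets of the same size and
degree profile, the proximity is recomputed, and after $R$ repetitions
(default 1000)

$$z = \frac{p_{\mathrm{obs}} - \mu_{\mathrm{null}}}{\sigma_{\mathrm{null}}},$$

with a one-sided lower-tail normal p-value: *small* distance is the signal,
so a two-sided test would double every p-value. The empirical p-value
$(1 + \#\{p_{\mathrm{null}} \le p_{\mathrm{obs}}\})/(R+1)$ is always
reported alongside; when $\sigma_{\mathrm{null}} = 0$ the z-based p-value is
undefined and the empirical one is used, flagged in the output. A drug is a
candidate when $p \le \alpha$ (default 0.05, no multiple-testing correction
across drugs — the screen is a ranking device, not a confirmatory test).

Degree matching uses *degree bins*: nodes are grouped by exact degree and
adjacent degree groups are merged, ascending, until every bin holds at least
`min_bin_size` nodes (default 100; a short final group merges leftward).
A random module draws one node from the bin of each original node, without
replacement within the draw. On heavy-tailed graphs the top bin spans a wide
degree range; a larger `min_bin_size` trades degree fidelity for sampling
diversity, and the sampler fails loudly (rather than silently reusing nodes)
when a bin is exhausted.

### Randomizing one module or both

By default every repetition re-draws *both* modules, matching the
formulation of the reference distance distribution as the distance between
two random degree-matched groups. For calibration experiments the package
also offers `fix_disease = TRUE`, which randomizes only the drug module.
The distinction matters: real disease modules are localized (they
concentrate in one neighbourhood), while degree-matched random sets are
dispersed. When the observed statistic conditions on one fixed, localized
disease module but the null integrates over random ones, the null acquires
extra variance and a location offset, and p-values of truly random drugs are
no longer uniform. With `fix_disease = TRUE` the observed and null draws are
exchangeable by construction, and the empirical p-values of random drugs are
exactly uniform — this is the mode the package's calibration tests use, and
the mode we recommend whenever the disease module is held fixed across a
screen. Both modes give essentially the same ranking of drugs; only the
absolute calibration of the p-values differs.

## The validation stage

The screen says a drug is *near* the disease; it does not say the drug
pushes expression in the right direction. The in-silico validation stage
asks whether a drug's transcriptional signature opposes the disease's:

1. **Disease signature.** From paired tumor/normal expression:
   log2 transform (pseudocount 1, so zero abundances stay at zero), per-gene
   IQR filter (genes with IQR strictly below the 10th percentile of the
   gene-IQR distribution are removed — these carry no differential signal),
   per-gene paired t-test (two-sided, $df = n-1$), Benjamini–Hochberg
   adjustment, threshold 0.01 on the adjusted p-value. Significant genes
   split by the sign of the mean log2 difference into up- and down-regulated
   lists, ranked by absolute fold change. Genes whose paired differences
   have zero variance get $p = 1$ and stay in the universe rather than being
   excluded, keeping all pipeline stages aligned on the same gene set.
   Percentiles use linear interpolation between order statistics
   (`quantile()` type 7).
2. **Connectivity score.** Each drug contributes a ranked gene list
   (position 1 = most up-regulated by the drug). The top `tag_size`
   (default 150) disease up-genes and down-genes are located in the drug
   list and scored with the classic two-tag-set Kolmogorov–Smirnov
   connectivity statistic: with sorted tag positions $V_{(j)}$ among $n$
   genes, $a = \max_j (j/t - V_{(j)}/n)$, $b = \max_j (V_{(j)}/n -
   (j-1)/t)$, score $a$ if $a > b$ else $-b$. The combined score is
   $es = (es_{up} - es_{down})/2$ when the two one-sided scores disagree in
   sign, and 0 when they agree (contradictory evidence). A drug with
   $es < 0$ — disease-up genes at the bottom of its list, disease-down genes
   at the top — gets the binary **counteraction score 1**.

**A reconstruction note, prominently.** The connectivity scoring formula is
the 2006-style two-tag-set KS statistic with the same-sign-zero rule, as
used by the original Connectivity Map query tool. It is implemented here
from that definition (not by calling an external service), and it is the
largest reconstructed component of the package: the weighted-KS variant used
by later L1000 releases is deliberately out of scope. Two structural
properties worth knowing:

* The one-sided statistic is *not* exactly antisymmetric under list
  reversal: reversing the list maps the extrema to $a' = b - 1/n$ and
  $b' = a + 1/n$, so the score flips sign only up to a $1/n$ offset (the
  worked pair: tags $\{1,2\}$ of $n=10$ score $+0.8$, but their mirror
  $\{9,10\}$ scores $-0.9$). The *combined* $es$ does negate exactly under
  reversal in the generic case, because the offsets of the up and down
  components cancel.
* A random drug list lands in the counteracting sign pattern
  ($es_{up} < 0$, $es_{down} > 0$) with probability about 1/4, so the binary
  counteraction score has a substantial baseline rate on null drugs. The
  score separates planted "antidote" profiles from random ones cleanly, but
  its absolute percentage should be read against that baseline.

## Breast-cancer subtype context

For interpreting which cell line a breast-cancer drug signature should come
from, the package classifies patients into clinical surrogate subtypes from
ER/PR/HER2 receptor status (`classify_breast_subtype()`): the four luminal
combinations are clinically less aggressive, HER2-enriched and triple
negative more aggressive; the two ER−/PR+ combinations are not part of the
standard surrogate definitions and map to `Unclassified`. Note the two
"Luminal B-like" columns of the clinical table differ only in PR status; we
name them `LuminalB_like_PRpos`/`LuminalB_like_PRneg` to keep the mapping
injective, and both count as less aggressive. `summarize_subtypes()` rounds
percentages half-up to integer percent, the convention of the clinical
literature it mirrors.

## What the synthetic generators emulate

All tests run on synthetic data with known ground truth:

* `generate_interactome()` grows a connected preferential-attachment graph
  (seed pair, each new node attaches $m = 2$ edges to distinct nodes with
  probability proportional to degree, giving exactly $2(n-2)$ edges). This
  reproduces the property that stresses the null model hardest — a
  heavy-tailed degree distribution — but not the local clustering,
  community structure, or literature-bias of a curated interactome.
* `plant_modules()` builds a disease module as a truncated breadth-first
  ball (connected and localized, as disease modules are assumed to be) and
  a drug module either adjacent to it (`proximal`) or degree-matched random
  (`random`).
* `generate_paired_expression()` draws per-gene log2 baselines with
  per-gene biological spread, adds per-pair noise (sd `noise_sd`, default
  0.5 log2 units), and shifts `n_de` genes by `effect` times the noise sd
  with random sign. It is a lognormal model: it does not emulate RNA-seq
  count overdispersion, library-size artifacts, or correlated genes, so
  passing tests demonstrate correctness of the pipeline's statistics, not
  robustness to real RNA-seq pathologies.
* `generate_drug_rankings()` builds perfect "antidote" lists by inverting
  the disease signature, plus uniform random permutations.

Default study conditions used by the test-suite experiments: 500-node
graphs, disease modules of 15 genes, drug modules of 8–15 targets, 100–1000
null repetitions; expression matrices of 1000 genes x 20 pairs with 50
planted differential genes at effect 2. These sizes were chosen to have
clear statistical power (planted modules are detected at $|z| \approx 4$)
while remaining comfortable for routine runs.

## Numerical and degenerate-input choices

* All randomized functions take an explicit `seed` and restore the caller's
  RNG stream; identical seeds give bit-identical outputs, including the
  written TSV/JSON reports.
* Drugs failing preconditions (fewer than `min_targets = 2` mapped targets,
  no mapped target, or every target unreachable) go to a skip log attached
  to the screen result — never silently dropped.
* An empty disease signature (nothing passes the adjusted-p threshold) is a
  warning, not an error; downstream enrichment then fails per drug with `NA`
  scores and an explanatory warning.
* `screen()` shares one set of random module draws across the requested
  metrics within each drug (each random distance matrix is summarized five
  ways), which is statistically equivalent to independent nulls per metric
  for the marginal p-values and substantially faster.

## Known limitations

* Node identifiers are opaque strings; no identifier mapping between
  UniProt/Entrez/symbol namespaces is attempted.
* The interactome is undirected and unweighted; evidence-type filtering,
  directed signaling, and diffusion-based proximity variants are out of
  scope.
* The screen reports raw per-drug p-values (with an optional BH column left
  to the user via `bh_adjust()`); a drug passing $\alpha = 0.05$ is a
  candidate for follow-up, not a validated indication.
* False-positive estimation across the whole drug panel is not implemented;
  every screened drug receives a score.
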