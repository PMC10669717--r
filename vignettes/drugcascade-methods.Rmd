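---
title: "Methods: literature-mined networks, shortest drug-target cascades, and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: literature-mined networks, shortest drug-target cascades, and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugcascade)
```

# Overview

`drugcascade` implements a desk-scale version of a widely used
network-pharmacology workflow: mine a disease-associated protein list
from literature abstracts, induce a disease protein–protein interaction
(PPI) network from a reference catalogue, extract each drug's
receptor-anchored interactome, identify the shortest receptor→anchor
signal cascade, test the interactome for annotation enrichment, and
validate the cascade genes with qPCR/ELISA group statistics. The
motivating application is the question of how two first-line
anti-diabetic drugs (metformin, acting through PRKAB1, and glimepiride,
acting through KCNJ11) can stimulate brain-derived neurotrophic factor
(BDNF) in type 2 diabetes, where reduced BDNF accompanies cognitive
decline.

This vignette records the model choices, the tunable parameters and
their defaults, the numerical decisions, and what the synthetic-data
validation does and does not establish.

# Corpus mining

## Curation

Manual literature curation (study-type screening, species checks) is
modeled as mechanical filters: a record is retained iff its year falls
in `[year_min, year_max]` (default 1990–2023), it contains at least one
inclusion keyword as a case-insensitive substring, and it contains no
exclusion term (e.g. "meta-analysis", "mouse model"). Anything genuinely
semantic is out of scope. Duplicate record ids collapse to their first
occurrence.

## Dictionary matching

Gene mentions are found by lexicon lookup, not statistical NER. The
matcher uppercases both text and lexicon (case-insensitive token
matching), requires word boundaries — the characters flanking a hit must
be non-alphanumeric or the string edge, so `BDNF-dependent` yields a
BDNF hit but `xBDNFx` does not — and resolves overlaps leftmost-longest:
scanning left to right, the longest candidate at the earliest unconsumed
offset wins. Offsets are 0-based, half-open, and the recorded surface is
exactly the text slice.

Two rails guard the lexicon itself: surfaces shorter than 3 characters
are blocklisted unless explicitly whitelisted (two-letter symbols are
pervasive false positives in prose), and any surface claimed by two
canonical symbols is ambiguous and is blocklisted (or rejected,
configurable) at load time.

## PMI weighting

Disease association is weighted by *document-level* pointwise mutual
information in log base 2:

$$\mathrm{PMI}(x, d) = \log_2 \frac{n_{xd}\,N}{n_x\,n_d}$$

An abstract contributes at most 1 to every count regardless of repeated
mentions; this makes PMI invariant to within-document repetition, which
is a tested property. PMI is 0 exactly at independence and increases
monotonically in the joint count. Two deliberate choices:

* **Zero joint count.** `compute_pmi()` returns a `-Inf` sentinel and
  `rank_proteins()` excludes such symbols by default. An optional
  add-0.5 continuity correction (applied to zero joints only, so
  observed co-occurrence is never perturbed) is available behind a flag.
  Silently imputing evidence for never-co-occurring symbols would be
  worse than excluding them.
* **Corpus-wide counting.** PMI is computed over document co-occurrence
  across the whole curated corpus rather than per abstract; a
  per-abstract statistic would be a binary indicator in disguise.

The PMI threshold that decides which proteins count as
"disease-associated" has no defensible universal value; it is a
configuration parameter (`min_pmi`, default `-Inf` plus the finite-PMI
rule, with `min_docs` for minimum support).

# Disease network and drug interactomes

The disease network is the subgraph of a user-supplied reference
catalogue induced on the mined protein list: edges whose **both**
endpoints were mined. Edges are undirected, unweighted, canonicalized
(lexicographic endpoint order), with self-loops and duplicates dropped
at load. Mined proteins touching no retained edge are kept as degree-0
nodes by default so the full mined list remains available as an
enrichment universe (`keep_isolated = FALSE` drops them).

Because public PPI catalogues differ by source and version, the
catalogue is an input file, and the package ships a small fixture
catalogue whose topology encodes the two cascades above plus longer
decoy routes.

## Shortest cascades

"Shortest" is hop count on the undirected graph; path order from
receptor to anchor is read as the signalling direction.
`shortest_cascade()` returns **all** minimum-hop simple paths (across
all of a drug's receptors by default; per-receptor behind a flag),
sorted by (length, lexicographic node sequence), and designates the
first as canonical. Returning all ties and picking a deterministic
representative avoids both nondeterminism and silent information loss.
A receptor equal to the anchor yields the trivial single-node path.

## Interactome hop budget

"All possible connections" between receptor and anchor is unbounded and
explodes combinatorially, so `extract_interactome()` enumerates simple
paths within a hop budget, default *shortest distance + 2*. This keeps
the neighbourhood bounded and reproducible while retaining the
hub-and-cascade shape around the shortest path; the budget is
configurable where a wider neighbourhood is wanted. An unreachable
anchor produces an empty interactome with a warning flag rather than an
error, so multi-drug runs continue.

# Enrichment

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ with term sets intersected with the universe first;
`stats::phyper` accumulates the tail in log space, and the
implementation is tested to machine precision against draw-by-draw
enumeration for all parameter sets with $N \le 12$. Following the
workflow being reproduced, the significance filter is the **raw**
p-value at `alpha = 0.01`; Benjamini–Hochberg adjustment is available
behind a flag (`adjust = TRUE`) for users who prefer FDR control. The
universe defaults to the disease network's node set and is configurable,
since the appropriate background is study-specific.

# Expression statistics

## 2^(−ΔΔCt)

Technical replicates are averaged to one Ct per (sample, gene) before
any statistic (anything else is pseudo-replication). Then per sample
ΔCt = Ct_gene − Ct_reference (reference default GAPDH), ΔΔCt subtracts
the calibrator group's mean ΔCt per gene, and fold = 2^(−ΔΔCt). The
calibrator defaults to the healthy-control group, matching the
convention of expressing patient groups relative to controls; by
construction the calibrator's mean ΔΔCt is 0 and its geometric-mean
fold is 1 on every dataset, which is asserted in the tests. Per-sample
baseline shifts (loading differences) cancel in ΔCt, another tested
invariant. No amplification-efficiency (Pfaffl) correction is applied —
the plain 2^(−ΔΔCt) method is the target of this implementation.

Group comparisons are run on per-sample fold values by default (what
relative-expression bar charts display), with `value = "delta_ct"`
available as the statistically better-behaved alternative.

## ANOVA and Tukey HSD

One-way fixed-effects ANOVA with $F = \mathrm{MSB}/\mathrm{MSW}$ on
$(G-1, \sum n_g - G)$ degrees of freedom; the degenerate all-means-equal
case returns $F = 0, p = 1$. Tukey HSD uses the studentized-range
distribution with Tukey–Kramer standard errors for unequal group sizes,

$$q_{ij} = \frac{|\bar y_i - \bar y_j|}{\sqrt{\tfrac{\mathrm{MSW}}{2}\left(\tfrac{1}{n_i}+\tfrac{1}{n_j}\right)}}.$$

The adjusted p-values are validated against an independent
studentized-range CDF computed by nested numerical integration (to
1e−6), and the null calibration (4 × 30 normal samples) is checked by
simulation to reject at 5% ± 2%. Because published figures sometimes
star unadjusted comparisons, `group_comparison()` reports both Tukey
adjusted and pooled-variance unadjusted pairwise p-values; the
`significant` flag uses the Tukey values at `alpha = 0.05`.

## ELISA quantification

The standard curve is linear least squares by default — the bundled
fixtures operate in the mid-range where the kit response is close to
linear — with a four-parameter logistic
$A(c) = d + (a-d)/(1+(c/c_{50})^b)$ available since the true sandwich
immunoassay response is sigmoidal. The 4PL is fitted by
Levenberg–Marquardt from data-driven starts (`a` = blank absorbance,
`d` = 1.05 × top standard, `c50` = concentration nearest half-maximal
response, `b` = 1). Interpolation inverts the fitted model only inside
the absorbance span of the standards; out-of-range samples are flagged
and get `NA` rather than an extrapolated concentration. Replicate
absorbances are averaged per sample before interpolation.

# Synthetic data: what it emulates, and what it does not

The generators are pure functions of their spec (including the seed;
the caller's RNG stream is saved and restored) and every planted
quantity is written to a ground-truth sidecar, so each pipeline stage
can be validated by recovery:

* `simulate_corpus()` draws disease membership and symbol mentions
  independently per document with the spec's probabilities, embeds
  symbols with proper word boundaries (a hard mode adds confusable
  `xSYMBOLx` substrings to exercise the matcher), and records exact
  counts.
* `simulate_network()` adds planted receptor→anchor paths to an
  Erdős–Rényi background and then breaks any alternative
  receptor→anchor route shorter than `min_decoy_length` by removing one
  of its non-planted edges, so the planted cascade is the *strict*
  shortest — making planted-path recovery an exact, not probabilistic,
  expectation.
* `simulate_expression()` encodes planted fold changes as per-group
  mean ΔCt offsets (`ΔCt = base − log2(fold)`), draws a per-sample
  baseline (SD 0.5 cycles, cancelling in ΔCt) and per-replicate
  technical noise. Defaults mirror the study design: four groups
  (untreated disease, metformin, glimepiride, healthy controls) of 30
  samples, GAPDH reference, triplicate measurements — the standard qPCR
  plate layout — technical SD 0.3 cycles, and fold changes
  qualitatively matching the reported direction of effects (targets
  reduced untreated; APP doubled under metformin; AP2M1/ESR1/BDNF
  raised, BDNF doubled, under glimepiride).
* `simulate_elisa()` generates standards from a stated response curve
  plus absorbance noise (SD 0.01) and group-structured samples; default
  serum concentrations sit in the 14–25 ng/mL range typical of adult
  serum BDNF.

What passing these tests shows: the arithmetic, search and inference
machinery is correct under its stated model. What it does not show: the
generators make no attempt at realistic biomedical prose (no synonymy
or ambiguity beyond the lexicon), real PPI topology (no scale-free
degree structure), amplification-efficiency drift, or heavy-tailed
expression noise — so recovery rates here do not predict performance on
real corpora or real patient data.

# Validation problem sizes

The test-suite and acceptance checks use: exhaustive simple-path oracles
on 500 random graphs of ≤ 12 nodes; draw-enumeration hypergeometric
checks for every parameter set with N ≤ 12; 500 seeded 20-document
corpora for PMI recounts; 200 seeded four-group expression datasets for
fold recovery (planted fold 2.0 expected within [1.8, 2.2] in ≥ 95% of
runs — with triplicate averaging the per-run success probability is
about 0.97 under the normal model); 1,000 null ANOVA simulations; and
200 planted-enrichment runs against a 50-term, 500-gene universe. These
sizes give the property checks enough resolution while keeping the
default test run quick on a laptop.

# Known limitations

* Matching is dictionary-bound: unlisted synonyms, misspellings and
  species ambiguity are invisible.
* The reference catalogue entirely determines reachability; cascade
  counts and intermediary identities are catalogue-dependent and the
  package deliberately does not claim to reproduce any particular
  published interactome's node counts.
* The undirected-graph reading of "downstream activation" is a
  convention, not biology; direction is imposed by path order only.
* Raw-p enrichment filtering reproduces the workflow's convention;
  users testing many collections should prefer `adjust = TRUE`.
* The pipeline is single-process and in-memory; corpora of hundreds of
  thousands of abstracts would need a streaming matcher.
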