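---
title: "Scoring yeast two-hybrid screens and assembling a confidence-ranked interactome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring yeast two-hybrid screens and assembling a confidence-ranked interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(y2hnet)
```

## The problem

A domain-oriented yeast two-hybrid (Y2H) campaign screens each bait protein
(or bait domain) against a random-primed cDNA fragment library and returns,
per screen, a pile of sequenced positive clones: intervals on prey proteins.
Turning that pile into a usable protein–protein interaction (PPI) network
requires three inferential steps, all of which `y2hnet` implements:

1. **SID assembly** — overlapping clone fragments on one prey are merged
   into families, and each family's common core is the *selected
   interacting domain* (SID), the minimal region sufficient for the
   interaction.
2. **Confidence categorization (PBS)** — each bait–prey pair is assigned a
   predicted biological score category from A (best) to E (promiscuous),
   using clone coverage, reciprocal detection, interaction cycles, and
   cross-screen promiscuity.
3. **Network assembly and filtering** — categorized interactions are merged
   into an undirected network, summarized topologically, and reduced to a
   high-confidence (HC) sub-network by rescuing low-confidence edges with
   orthogonal evidence.

Around this core the package provides the statistics used to audit such a
network (SID–domain overlap enrichment, shared-GO-pair tests, EASE
enrichment, disease-class over-representation, locus candidate mining) and
quantifiers for the two bench validation assays whose outputs are numeric
(proximity ligation spot ratios, colocalization Pearson coefficients).

## Fragment families and SIDs

A SID only exists where a *common* core exists. A chain of merely pairwise
overlapping fragments (10–100, 50–150, 140–200) has no shared residue, so
family construction cannot be plain single-linkage contigging. We define a
family as a maximal group with a non-empty common intersection, built
greedily over the canonical fragment order `(start, stop, clone_id)`: the
first unassigned fragment seeds a family; each later unassigned fragment
joins if it intersects the family's *running core*; the scan repeats until
all fragments are assigned. Overlap means at least one shared residue
(closed 1-based amino-acid intervals; touching counts). Sorting first makes
the partition independent of input row order, which the test suite asserts
by permutation.

```{r}
frags <- tibble::tibble(prey_protein = "P1",
                        clone_id = c("c1", "c2", "c3"),
                        frag_start = c(10L, 50L, 140L),
                        frag_stop = c(100L, 150L, 200L))
assemble_families(frags)
```

A SID is a *singleton* when it is supported by a single distinct fragment
interval — one clone, or several clones with identical boundaries. This
distinction drives the D category below. Families are assembled within a
screen; the cross-screen view only enters through promiscuity scoring. One
prey may carry several SIDs in a screen (two binding sites yield two
families); each is counted separately.

## The PBS decision rules

Categories are assigned with strict precedence:

| order | condition | category |
|---|---|---|
| 0 | prey on the known-false-positive list | excluded |
| 1 | SID found under more than `promiscuity_threshold` (default 10) *unrelated bait proteins* | E |
| 2 | singleton SID evidence in every supporting screen | D |
| 3 | otherwise: fragment-support score, reciprocal detection forces A, triangle membership upgrades one level (cap A) | A / B / C |

"Unrelated baits" means distinct bait *proteins*: two domains of one bait
are related and count once. Promiscuity is counted within the supplied
screen registry; a facility running many unrelated campaigns would count
across all of them, so promiscuity estimates from a single small registry
are conservative.

The original campaign scored A–C with an e-value whose computation is
proprietary to the screening facility; its published description is
qualitative ("many overlapping prey fragments"). `y2hnet` therefore scores
A–C with a transparent surrogate: the number of distinct (non-identical)
fragment intervals supporting the interaction, summed over independent
screens, with defaults ≥6 → A, ≥4 → B, ≥2 → C. The thresholds are
configuration, and `assign_pbs()` accepts a pluggable p-value scorer that
honours the conventional cutoffs (1e-10 / 1e-5 / 1e-2.5) for users who have
a calibrated model. Two deliberate choices at rule boundaries:

* **E beats reciprocity.** The precedence between promiscuity and
  reciprocal detection is genuinely open; we let stickiness dominate
  (a promiscuous SID is suspect regardless of orientation) and emit a
  message for every such conflict so they can be audited.
* **D beats reciprocity too**, because precedence is total and singleton
  evidence is checked first; two screens that each contribute only a
  singleton still make a D.

These rules give two monotonicity properties the tests assert: raising the
promiscuity threshold never moves an interaction *into* E, and adding an
independent confirming screen never demotes a category.

## Network, topology, HC filter

`build_network()` merges ordered, per-screen interactions into unordered
edges; a merged edge takes the best category among its constituents.
Self-loops (homodimers) are kept as edges, contribute 2 to their node's
degree — so mean degree is exactly `2E/N` — and are excluded from density
and shortest-path computations, the standard graph-theoretic convention.
Mean shortest path is averaged over unordered node pairs of the largest
connected component; heterogeneity is the coefficient of variation of the
degree sequence (population sd / mean), a hubbiness measure; density is
`2E/(N(N−1))` without self-loops. Networks of this kind print a "mean
connectivity" in some reports that is not reproducible from any standard
definition given their node/edge counts; we therefore report the standard
metrics only and leave interpretation to the user.

The HC filter keeps every A–C edge and admits a D/E edge when at least one
of four rules holds: literature support, experimental confirmation
(co-immunoprecipitation, colocalization or PLA), GO sharing (a shared
biological-process cluster, or shared cellular-component *and*
molecular-function clusters), or a neuromuscular-disorder prey. Each
admitted edge records its admitting rule(s), the filter deduplicates edges
admitted by several rules, and applying the filter twice is idempotent.

## Annotation statistics

* **Shared GO pairs.** "Sharing" is shared membership in annotation
  *clusters* supplied as input (the style produced by functional annotation
  clustering tools), not raw GO term identity — clustering is upstream. The
  reported fraction uses all network PPIs as denominator, and the
  denominator is always reported alongside.
* **Background expectation.** Per bait, `Shared_i` counts proteome proteins
  sharing a cluster; the expected sharing frequency is
  `sum(Shared_i) / (n_baits × proteome_size)` (default universe 19220
  protein-coding genes). Observed vs expected is compared with a 1-df
  Pearson chi-square without continuity correction: the expected counts in
  the intended regime (hundreds of pairs) are large enough that the
  correction would only add bias.
* **Exact tests.** Domain enrichment uses a two-sided Fisher test on the
  SID-vs-proteome 2×2 table with Benjamini–Hochberg correction across
  domains; zero margins give p = 1 by convention. The EASE score decrements
  the overlap by one (floor 0, margins unchanged) before taking the
  one-sided hypergeometric tail, so a single-gene overlap can never appear
  enriched; EASE p is always ≥ the classical Fisher p. All exact tests are
  checked against brute-force enumeration for margins ≤ 30.

## Validation quantifiers

The PLA rule is per-cell ratio first, then mean: each cell contributes
`ppi_spots / prey_spots`, cells with zero prey signal are inconclusive and
excluded from the mean rather than counted as zeros, and the compartment
validates only when its mean ratio *strictly* exceeds 0.2 (a mean of
exactly 0.2 does not validate). A PPI validated in any compartment counts
as validated overall, with the compartments recorded — the alternative
(requiring all compartments) would penalize genuinely compartmentalized
interactions. Colocalization classes use half-open Pearson intervals:
low R ≤ 0.25 < medium R ≤ 0.5 < strong R ≤ 1, so the boundary values 0.25
and 0.5 fall in the lower class. The rollup marks a pair experimentally
supported when *any* technique is positive, ignoring inconclusive ones.

## The synthetic screen generator

`simulate_screen_set()` emulates the screening campaign statistics so the
whole pipeline can be exercised with known ground truth: fragment lengths
are truncated normal with mean 200 aa (~600 bp of coding sequence),
sd = mean/3, floored at 30 aa; an average of 155 positive clones per
screen; true interactions detected per screen with probability 0.9
(saturation screening); per-screen singleton noise; and sticky preys
recurring across a configurable number of unrelated bait screens. Planted
clones all cover their interaction domain, so the computed SID provably
contains it. Defaults (15 baits, 300 proteins, 60 planted PPIs, 20 noise
singletons per screen, 2 sticky preys of breadth 12) keep a 20-replicate
recovery experiment comfortably fast on one CPU while leaving every scoring
rule exercised; they are held fixed as the package's reference conditions.
Noise records are disjoint from planted and sticky pairs by construction,
and detection draws use their own seeded stream so that two simulations
differing only in clone budget share the same detection pattern (this is
what makes "more clones never hurts recall" testable on paired seeds).

What the generator does **not** model: mRNA-abundance bias in the library,
3-AT selective-pressure tuning, auto-activating baits, frame/UTR artifacts
of random priming, or biological correlations between GO annotation and
interaction truth (annotations are independent of planted edges). Passing
recovery tests therefore demonstrates that the scoring rules separate
coverage-rich true signal from singleton noise and promiscuity under the
stated geometry — not that the pipeline is robust to every artifact of real
screens.

```{r}
sim <- simulate_screen_set(sim_config(rng_seed = 42))
ints <- score_interactions(sim$screen_data)
recovery_report(ints, sim$truth)[c("recall_abc", "noise_abc_rate",
                                   "sticky_e_rate")]
```

## Degenerate inputs and numerical conventions

Empty screen tables parse to empty registries; an empty interaction set
gives an empty category table; a single-node network reports shortest path
as `NA`; zero-variance intensity channels give an undefined Pearson
coefficient (`NA`), not an error; all-inconclusive PLA measurements yield
the verdict `"inconclusive"`, distinct from `"not_validated"`. Identifier
matching across tables is exact after case-folding and stripping trailing
version suffixes; alias resolution is out of scope. Fragment coordinates
are amino-acid positions, 1-based and inclusive at both ends; nucleotide
inputs are not handled.

## Known limitations

The fragment-count surrogate for A–C is deliberately simple; it tracks the
qualitative definition of the categories but will not reproduce a
facility's exact e-values. Promiscuity measured within one campaign
under-counts relative to a cross-campaign registry. GO sharing depends
entirely on the granularity of the supplied cluster table. The simulator's
uniform fragment placement ignores 5'/3' library bias, which in real
screens shifts SIDs toward prey C-termini.
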