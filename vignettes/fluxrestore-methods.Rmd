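---
title: "Methods: from differential proteomes to restored metabolic flux"
author: "fluxrestore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from differential proteomes to restored metabolic flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxrestore)
```

# The question the pipeline answers

Given protein abundances from three groups of animals -- healthy controls
(`WT_VEH`), a disease model (`AD_VEH`) and the disease model under a
candidate treatment (`AD_NFP`) -- which metabolic reactions and metabolites
are pushed away from the control state by the disease and pulled back by
the treatment? The pipeline answers this with constraint-based metabolic
modelling: each sample's proteome conditions a genome-scale metabolic
network into a sample-specific model, fluxes are estimated per model, the
turnover (flux-sum) of every metabolite is profiled, and a three-group
classification labels the entities whose flux-sum rises in disease and
falls back under treatment.

# Stage by stage

## Differential proteome statistics

Protein intensities are analysed on the log2 scale, where the log-normal
noise of LC-MS intensity data is approximately Gaussian with constant
variance. Each protein is tested by fixed-effects one-way ANOVA across the
three groups (`anovaBH()`), and the Benjamini-Hochberg step-up procedure
controls the false discovery rate over all tested proteins at
`alpha = 0.05`. Z-scores (`zscoreNormalize()`) use the population standard
deviation (divisor *n*), the usual convention for expression heatmaps;
constant rows cannot be scaled and are flagged and mapped to zero rather
than dropped silently.

Significant proteins are clustered (`clusterDEPs()`) on their Z-scored
profiles with Euclidean distance and Ward's minimum-variance linkage, cut
at `k = 4`. We initially used average linkage, the common default of
proteomics GUIs, but at `k = 4` it reliably spends cut levels on isolated
ANOVA false positives (single proteins with extreme Z-profiles) and merges
two genuine response clusters; Ward's criterion absorbs such outliers into
their nearest bulk cluster and produced clean cuts in every simulation we
ran. The four clusters are then *relabelled* into fixed semantics --
1 = up in disease and renormalised by treatment, 4 = the mirror image,
2/3 = disease-insensitive but shifted by the treatment (possible
side-effects) -- by matching each cluster centroid against the four
archetype group-mean patterns and choosing the label permutation with the
highest total cosine similarity. Matching a permutation rather than
ranking single contrasts keeps the labels stable when a small noise
cluster happens to carry an extreme contrast.

Treatment-regulated proteins are selected by Tukey's honestly-significant
difference on the `AD_NFP` vs `AD_VEH` contrast (`tukeySelect()`), with
the Tukey-Kramer correction for the unequal group sizes, applied after the
ANOVA filter (ANOVA-then-post-hoc is the conventional chain; the filter
can be disabled by omitting the `dep` argument). Ties at exactly `alpha`
are excluded (strict inequality).

## Reaction evidence and context-specific model extraction

A sample's expression is mapped onto reactions through the
gene-protein-reaction rules: isozymes (`or`) add their abundances, enzyme
complexes (`and`) are limited by their scarcest subunit. The evidence
weight of reaction *j* is

$$w_j = \mathrm{clip}\left(\ln \frac{e_j}{\tau},\ \pm w_{\max}\right),$$

with `tau` the median reaction-level expression of that sample (so weights
are positive above the sample's own typical expression and negative
below), `w_max = 5` to keep single reactions from dominating, and a small
negative weight (-0.1) for reactions without any rule, a weak prior
against carrying unevidenced reactions. Exchanges and the biomass reaction
are neutral.

Extraction (`extractContext()`) maximises the summed weight of the kept
reactions subject to *flux consistency*: every kept reaction must be able
to carry nonzero steady-state flux within the kept set. Two searches are
provided. The exact mode exploits the fact that removing a reaction can
only block others, never unblock them, so a non-negative-weight reaction
is only ever excluded when it is blocked; the search space is therefore
the subsets of negative-weight reactions, each completed by its
flux-consistent closure, and full enumeration is affordable for up to a
dozen candidates. The greedy mode drops the most negative-weight reaction
whose closure-completed removal improves the objective, and stops when no
removal helps. The pipeline additionally anchors extraction with its
metabolic task -- biomass production at `v_min = 1e-3` flux units must
remain feasible -- because pure evidence maximisation on a sample whose
total evidence is negative can legally collapse to the empty model. The
task list here is biomass only; full task catalogues of tissue-model
pipelines are out of scope.

Gap-filling (`gapfillGrowth()`) then guarantees growth on the medium by
adding a minimum-cardinality set of parent-network reactions: exhaustive
over subset sizes up to 12 candidates, and an irreducible (minimal, not
necessarily minimum) repair beyond that. It is idempotent, and a second
call never adds anything.

Model quality (`qcModel()`) reports stoichiometric consistency (the
fraction of metabolites admitting strictly positive molecular masses
conserved by all internal reactions, an LP test), elemental and charge
balance from the species annotations, and metabolite connectivity.

## Flux estimation and flux-sum

Fluxes are estimated per context model by least absolute deviation
(`ladFit()`): minimise the summed absolute deviation between fluxes and
expression-derived targets subject to steady state, bounds, medium uptake
limits and the growth requirement. Targets (`expressionTargets()`) scale
the reaction-level expression linearly so that the most expressed targeted
reaction is aimed at its upper bound; reactions without rules, exchanges
and biomass carry no target. Deviations are measured on the net flux.
The LAD problem is a linear program with split deviation variables; its
optimum is generally a vertex and alternate optima exist, which is why all
group comparisons are made on replicate distributions (one model per
sample) rather than on a single flux vector.

The flux-sum of metabolite *i* (`fluxSum()`) is its total production at
steady state, $\Phi_i = \sum_j \max(S_{ij} v_j, 0)$, identically half the
total absolute turnover; it quantifies how much of the metabolite the
network (re)generates per unit time.

## Three-group comparison and restoration labels

`compareAll()` builds one record per reaction (net flux) and per
compartment-qualified metabolite (flux-sum; the same species in different
compartments counts separately). An entity absent from a sample's model
contributes zero -- absence of all its reactions means no capacity to turn
it over -- and the record is flagged. Group tendencies use medians, robust
at n = 3. The restoration rule (`classifyRestoration()`): an entity whose
disease median exceeds the control median and whose treated median falls
below the disease median is a *decreased* flux-sum; when both Wilcoxon
rank-sum tests (disease vs control, treated vs disease) reject at
p < 0.05 it is *significantly decreased*; the mirrored pattern gives the
increased labels. Rank-sum p-values are exact by enumeration for small
tie-free samples and use the normal approximation with tie and continuity
corrections otherwise. No multiplicity correction is applied across
entities, matching the per-entity p < 0.05 rule the classification is
defined with; a BH layer can be applied downstream if desired.

One property of this rule deserves emphasis: the two tests share the
disease group, so their rejections are positively dependent. Under a null
generator at the study's group sizes we measured P(reject) of about 0.037
and 0.049 for the single tests (below nominal because the exact tests are
discrete) but a joint significant-label rate of about 0.4% -- well below
either single test's level, yet above the 0.25% that naive independence
(alpha squared) would suggest. The tests assert the provable bound (the
smaller single-test level) and a 1% ceiling, not the independence product.

## Sample embedding

`embedSamples()` projects samples into two dimensions with UMAP, either on
proteome abundance profiles (neighbourhood size 5) or on binary
reaction-presence vectors of the context models (neighbourhood size 11),
single-threaded and seeded for determinism. The embedding is a
visualisation aid; tests only smoke-test separation and determinism.

# The synthetic study

`generateToyNetwork()` builds a deterministic three-compartment network
(extracellular, cytosol, mitochondrion; ~29 reactions at the default
3-round configuration) around the mitochondrial carnitine shuttle and
beta-oxidation: fatty acid uptake, cytosolic activation by an isozyme
family, the carnitine shuttle, `nRounds` beta-oxidation rounds by
three-subunit complexes, and acetyl-unit release into the biomass
precursor pool. A glucose branch feeds the same pool, so growth never
depends on the fatty-acid branch. Activation and shuttle steps carry
`or`-rules and each oxidation round an `and`-rule, the association pattern
typical of this pathway. Species compositions are assembled from fixed
moieties (the acetyl unit is C2H4O2, so glucose cleaves exactly into three
units), every species is neutral, and condensations conserve moieties
exactly, so all four quality metrics are 1.0 by construction. Bounds are
finite (default 100 flux units, uptakes 10) -- the LP layer requires
finite boxes.

`simulateProteome()` plants the ground truth: all fatty-acid-branch genes
(plus extras) form cluster 1, low in control (offset -2 log2 below the
bulk) and elevated by +3 log2 in disease; respiration genes and extras
form the mirrored cluster 4; clusters 2/3 are treatment-shifted only; a
~400-protein background is null. Noise is log-normal with CV 0.2, a
typical within-group spread for LC-MS intensities. Group sizes default to
3/9/6 (control/disease/treated). The offset and effect sizes were fixed at
design time so that the planted branch sits clearly below the median
reaction-expression threshold in control samples and clearly above it in
disease samples even after `and`/`or` aggregation; an early draft in which
most rule-bearing reactions belonged to the planted branch taught us that
the per-sample median threshold erases a contrast planted on the majority
of reactions, which is why every transport also carries a housekeeping
single-gene rule. The planted restored metabolites are exactly the species
touched only by branch reactions (acyl-CoAs, acyl-carnitines, carnitine
and CoA pools).

What the simulation does *not* emulate: peptide-level identification and
missing values, protein-to-gene mapping ambiguity, correlated noise across
proteins, regulatory effects not visible in abundances, and the scale of a
real genome-scale model (thousands of reactions). Passing the end-to-end
tests therefore demonstrates that the machinery is correct and that the
statistical rules behave as designed -- not that real tissue data would
yield comparable recovery.

# Numerical choices

All constraint-based subproblems are small dense linear programs solved by
an internal two-phase primal simplex with Bland's rule, which terminates
on the highly degenerate systems steady-state stoichiometry produces; the
optimal basis is re-solved against the original constraints, giving
solutions accurate to ~1e-12 (no general-purpose LP package is available
in this R stack, and the one general-purpose simplex we tried fails with
singular-basis errors on degenerate network LPs). Flux-consistency uses a
sound dead-end pre-filter (a metabolite without a possible producer or
consumer blocks its reactions) followed by one batched capped-activation
LP for irreversible reactions and individual probes for the rest, at
tolerance 1e-6. Steady state is enforced to |S v| <= 1e-6 and verified in
tests; the flux-sum production/turnover identity holds to 1e-9. Exact
extraction breaks objective ties towards fewer reactions; greedy tries
candidates most-negative-first and never revisits a failed candidate.
Degenerate inputs (constant protein rows, empty reaction subsets, entities
absent from all models, contexts without a biomass reaction) are either
flagged or produce informative errors rather than silent results.

Problem sizes used by the test-suite and the acceptance script -- a ~29
reaction network, ~530 proteins, 18 context models per simulated study, 20
simulated studies for the Monte-Carlo properties, 2,000 null entities for
the false-label rate -- were chosen so that exhaustive oracles (full
subset enumeration, 5,005-arrangement rank-sum enumeration) remain
feasible alongside the pipeline itself.

# Known limitations

* The LP layer is dense and intended for networks of at most a few
  hundred reactions; genome-scale models need an external solver.
* Exact extraction is exponential in the number of negative-evidence
  reactions and falls back to greedy beyond a dozen candidates; greedy
  carries no optimality guarantee off separable instances.
* Gap-filling beyond 12 candidates returns an irreducible, not provably
  minimum-cardinality, repair set.
* The restoration classification tests each entity marginally; entities
  are not independent (they share the fitted flux vectors), so the
  labelled set should be read as a ranking with per-entity error control,
  not a family-wise statement.
* LAD targets assume expression is proportional to attainable flux up to
  a common scale; kinetic and thermodynamic limits are ignored.
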