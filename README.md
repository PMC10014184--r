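# fluxrestore

Integrated differential proteomics and constraint-based metabolic
modelling for three-group treatment studies: which metabolites does a
disease push away from the control state, and which of those does a
treatment pull back?

The package is built for the control / disease / treated design common in
preclinical work (here labelled `WT_VEH`, `AD_VEH`, `AD_NFP`). It takes a
protein-abundance matrix, a metabolic network in SBML (Level 3 + fbc v2)
and a growth medium, and runs:

1. **Proteome statistics** — per-protein one-way ANOVA with
   Benjamini–Hochberg FDR control, row Z-scores, hierarchical clustering
   of the significant proteins into four response clusters
   (1 = disease-up/treatment-restored, 4 = the mirror, 2/3 =
   treatment-only shifts), and Tukey–Kramer selection of
   treatment-regulated proteins.
2. **Context-specific model extraction** — per sample, reactions are
   scored by mapping expression through the gene–protein–reaction rules
   (isozymes add, complex subunits take the minimum) as
   `w_j = clip(ln(e_j / τ), ±w_max)` with `τ` the sample's median
   reaction-level expression; extraction maximises Σ w_j over kept
   reactions subject to every kept reaction carrying steady-state flux
   (exact enumeration on small instances, greedy pruning otherwise),
   anchored by biomass production; gap-filling restores growth with a
   minimum-cardinality addition set; model quality is reported
   MEMOTE-style (stoichiometric consistency, mass/charge balance,
   connectivity).
3. **Flux estimation** — least-absolute-deviation (LAD) fitting of fluxes
   to expression-derived targets under `S·v = 0`, bounds, medium limits
   and a growth requirement, then per-metabolite **flux-sums**
   `Φ_i = Σ_j max(S_ij · v_j, 0)` (total production ≡ half total absolute
   turnover).
4. **Restoration classification** — per reaction and per
   compartment-qualified metabolite, group medians plus two Wilcoxon
   rank-sum tests (disease vs control, treated vs disease; exact for
   small tie-free samples): an entity elevated in disease and lowered
   again by treatment, with both tests at p < 0.05, is labelled
   `significantly_decreased_flux_sum` (mirror rule for increases).
   UMAP embeddings of proteome and model-content profiles are included.

Because studies of this shape rarely ship reusable raw data, the package
also contains a fully synthetic study: a deterministic toy
carnitine-shuttle / β-oxidation network spanning three compartments
(`generateToyNetwork()`) and a proteome simulator with planted ground
truth (`simulateProteome()`) — the fatty-acid branch is elevated in
disease and renormalised by treatment, so the branch's acyl-CoA and
acyl-carnitine pools are known restored metabolites the pipeline should
recover. Every stage is tested against independent brute-force oracles
(sum-of-squares ANOVA, studentized-range Tukey, rank-sum enumeration,
exhaustive subset search for extraction and gap-fill).

## Worked example

```r
library(fluxrestore)

net <- generateToyNetwork()
net
#> MetabolicNetwork: 29 metabolites x 29 reactions
#>   compartments: c, e, m
#>   biomass: BIOMASS | exchanges: 8 | reactions with GPR: 20

sim <- simulateProteome(net, seed = 1)      # 3 + 9 + 6 samples
res <- runPipeline(net, sim$proteome)

sum(res$dep$significant)                    # differentially expressed proteins
#> [1] 129
length(res$regulated$upregulated); length(res$regulated$downregulated)
#> [1] 52
#> [1] 74

res$modelStats$meanCounts
#>    group meanReactions meanMetabolites
#> 1 AD_NFP            17        15.00000
#> 2 AD_VEH            20        21.66667
#> 3 WT_VEH            17        15.00000
```

The treated-group models have returned to the control-group size, while
the disease models carry the extra fatty-acid-branch reactions. The
comparison table contains the restored metabolites:

```r
cmp <- res$comparison
head(cmp[cmp$kind == "flux_sum" &
         cmp$label == "significantly_decreased_flux_sum",
         c("entity", "median_wt", "median_ad", "median_nfp",
           "p_ad_vs_wt", "p_nfp_vs_ad")], 5)
#>      entity median_wt median_ad median_nfp p_ad_vs_wt p_nfp_vs_ad
#>     accoa_m         0        20          0     0.0155     0.00126
#>       coa_m         0        20          0     0.0155     0.00126
#>      prec_m         0        20          0     0.0155     0.00126
#>  acyl2coa_m         0         5          0     0.0155     0.00126
#>  acyl4coa_m         0         5          0     0.0153     0.00124
```

Mitochondrial acyl-CoAs, acetyl-CoA and the CoA/carnitine pools turn over
at ~5–20 flux units only in the disease models and not at all in control
or treated models — the planted restoration pattern. Recovery against the
simulator's ground truth:

```r
restorationRecovery(res$comparison, sim$truth)[c("recall", "falseDiscovery")]
#> $recall
#> [1] 1
#> $falseDiscovery
#> [1] 0
```

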