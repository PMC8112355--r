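---
title: "From GC-MS sterol profiles to pathway models and ancestral support maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GC-MS sterol profiles to pathway models and ancestral support maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolpath)
```

`sterolpath` chains four inference stages that are usually run separately:
semi-quantitative GC-MS sterol profiling, ab-initio biosynthesis pathway
modelling from molecular transformations, gap-filling for specialized
metabolites, and stochastic character mapping of pathway-support states on a
phylogeny. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was genuinely
open.

## The molecule model: fact sets on shared steroid numbering

Sterols share a numbered carbon skeleton, so a molecule can be represented
relationally: a set of `atom(position, element)` and
`bond(position1, position2, order)` facts with positions fixed by the
standard numbering (`c1..c27` for the cholestane core and side chain, `o1`
for the 3-hydroxyl oxygen). Hydrogens are implicit; a 3-ketone is the
`c3=o1` double bond; the 9&beta;,19-cyclopropane ring of cyclosterols is an
explicit `c9-c19` bond.

Because positions are shared across molecules, comparing two sterols needs
no subgraph-isomorphism search: a molecular transformation is the *signed
set difference* of two fact sets. The same chemical operation performed on
different substrates — say, the &Delta;^24^-reduction that turns
desmosterol into cholesterol or cycloartenol into cycloartanol — yields the
*identical* diff, which is what lets a reaction observed in one context be
recognised elsewhere.

Two labelling conventions deserve a note. Ring methyls of the C30
precursors are `c28`/`c29` (the 4&alpha;/4&beta; pair, removed by the two
4-demethylations) and `c30` (the 14&alpha; methyl); side-chain alkyl
carbons of C28/C29 sterols are `c28` (the 24-methyl(ene) or ethylidene CH)
and `c29` (the terminal CH~3~). These two uses never co-occur in the
packaged model because side-chain alkylation is placed after complete
demethylation: the early 24-alkylated, still-ring-methylated intermediates
of the land-plant route (cycloeucalenol, obtusifoliol and relatives) are
outside the packaged registry. This is a deliberate granularity choice —
none of those intermediates is observable in the profiling panel, and a
parallel methylated demethylation series would double the registry without
adding testable structure.

### Context facts

A pure diff cannot express a substrate requirement that the operation does
not itself modify. The canonical example is side-chain alkylation: adding
the `c29` methyl to `c28` is, as a diff, just two added facts, yet the
chemistry requires the &Delta;^24(28)^ double bond to be present. Each
transformation therefore also stores *context facts*: the substrate facts
adjacent to the touched (anchor) positions that were present, unchanged, at
derivation time. Context is checked when a transformation is applied or
used for deduction, but it is **not** part of transformation identity: two
transformations with equal removed/added sets are one type. That keeps the
mozukulin chain's final &Delta;^24^-reduction the *same* reaction type as
the sterol one (it is reported as a substrate-class variant, acting on a
sterone rather than a sterol) instead of a spurious novel type.

### Relaxed (positional) matching

Beyond identity, two transformations match as *positional variants* when a
bijection between their anchor positions — carbons onto carbons, oxygens
onto oxygens — makes their diffs equal: the same operation at a different
skeletal position. The search is brute force over anchor permutations,
which is exact and fast because no transformation in the model touches more
than five positions. This is the formal version of the relaxed
transformation concept used for gap-filling ("type hIIc" homology in the
older comparative-biochemistry vocabulary).

## Pathway inference

A knowledge base bundles a molecule registry, per-species detection
statuses, known (database-registered) reactions, a strict transformation
library derived from them, a source metabolite, and target end metabolites.
Inference proceeds in three steps.

**Deduction.** Every ordered registry pair whose fact diff is identical to
a library transformation (with context present in the substrate) is a
deduced reaction. This is exhaustive and deterministic.

**Intermediate closure.** If a target is unreachable, unobserved structures
are generated by applying library transformations to registry molecules.
The closure depth escalates one step at a time and stops at the first depth
restoring reachability: the minimal number of consecutive unobserved steps
is what the data support, and deeper closures only add off-chain
structures. Generated structures must pass skeleton validation; a budget
(default 500 structures) guards against adversarial libraries. Afterwards,
inferred structures not on a distance-minimal connection to a target that
needed them are discarded — an inferred detour parallel to an observed
chain can never reduce the unobserved-node count, so dropping such
structures does not change the optimum but keeps chain enumeration
tractable.

**Chain selection.** Among candidate source→target chains the pathway
minimises, in order: (1) the number of unobserved
(`inferred_intermediate`-flagged) nodes, (2) the total edge count, (3) the
lexicographic edge order, subject to the constraint that a molecule
detected in an in-scope species must lie on some chain whenever
topologically possible. The constraint is what places zymosterol on the
cholesterol chain — forcing the second sterol-4-demethylation before the
&Delta;^8^→&Delta;^7^-isomerization — when zymosterol is detected; with
zymosterol undetected both orders tie and are reported, the chosen one by
the deterministic tie-break and the other among the `alternatives`. Chain
combinations are searched exhaustively when the product space is small
(the packaged models are) and by a deterministic per-target selection
otherwise. Non-chosen admissible edges are retained with an `optional`
flag, not discarded: they are possible routes, just not the minimal model.

The optimisation criterion itself is a design choice — the minimal-model
preference (fewest hypothetical intermediates first) mirrors how consensus
pathway figures are drawn, but nothing in the data rules out the tying or
slightly longer routes, and the reported alternatives should be read in
that light.

## Gap filling for specialized metabolites

When targets stay unreachable under the strict library, gap-filling
escalates through relaxation levels:

* **L0** — strict library only;
* **L1** — transformations imported from an auxiliary library (reactions
  documented in other pathways or organisms);
* **L2** — positional variants of any known transformation, instantiated
  from registry molecule pairs.

The admitted set of novel types is minimal: fewest L2 variants first, then
fewest L1 imports, then lexicographic names, searched lazily in cost order.
On the packaged mozukulin knowledge base this admits exactly three types:
the sterone-&Delta;^1(2)^-desaturation (imported; known from bacterial,
fungal and animal steroid catabolism), the sterone-23-hydroxylation
(imported; brassinosteroid synthesis), and the sterone-23-reduction, an L2
positional variant of the animal/fungal sterone-3-reduction that brown
algae lack.

Two encoding decisions here were open and are worth recording. First, the
isolated mozukulin structures are not published as machine-readable
encodings, so the packaged mozukulin molecules are synthetic stand-ins
(flagged as such in the fixture file) consistent with the branch's reaction
chemistry. Second, the C-23 oxygenation is encoded at the ketone level —
the hydroxylation and its follow-up oxidation collapsed into one step — so
that the 23-reduction (ketone → alcohol, exactly the positional analogue of
the 3-ketosteroid reduction) yields the 23-hydroxyl of mozukulin A. This is
the only encoding in which the branch needs precisely the three documented
novel reactions.

The curation rule downstream is deliberately conservative:
`export_gsmn_additions()` emits a reaction-addition table for metabolic
network curation only under strong species-level support (cholesterol
*and* desmosterol detected); otherwise it emits an empty table with the
rationale recorded.

## Semi-quantitative GC-MS profiling

Identification uses two orthogonal filters: the linear
(temperature-programmed) retention index against a C7–C40 alkane ladder,
`RI = 100(n + (rt - t_n)/(t_{n+1} - t_n))`, and the cosine similarity
between the peak's spectrum and a standard's reference spectrum over the
scanned m/z 50–500 range. A peak matches when `|ΔRI| ≤ ri_tol` (default 10
index units) *and* cosine ≥ `s_min` (default 0.8); among qualifying
standards the best spectral score wins, ties broken by smaller `|ΔRI|`.
The linear rather than logarithmic index is used because the oven program
is temperature-ramped. Both tolerances are configurable; the defaults are
ordinary practice for an HP-5-type column. Commercial standards are epimer
proxies for the 24-alkyl sterols (campesterol for 24-methylcholesterol and
so on); identifications carry the proxy note rather than pretending to an
epimer resolution GC-MS cannot deliver.

Quantification is internal-standard based with averaged relative response
factors: `RRF_x` is the mean of `(area_x/area_IS)/(conc_x/conc_IS)` over
all calibration levels of both standard mixes — a linear-through-origin
calibration, with per-mix means and their spread reported as a diagnostic.
Sample masses then follow from
`mass_x = (area_x/area_IS) · IS_amount / RRF_x`, with defaults of 60 mg dry
weight per sample and 5 µg of 5&alpha;-cholestane internal standard.
Relative abundances are percentages of the total; a compound below 0.01 %
is reported `nd` (not detectable). Squalene is tabulated with the sterols
and included in the percentage denominator by default (a configuration
switch excludes it). Quantification is invariant to any global rescaling of
areas, and detected percentages sum to 100 within numerical tolerance.

## Stochastic mapping of pathway support

Species-level support for the late side-chain-reductase cholesterol
pathway is classified from the profiles — `strong` (cholesterol and
desmosterol detected), `weak` (cholesterol only), `none` — and mapped on a
phylogeny under a symmetric-rates CTMC (SYM: `q_ij = q_ji`, one free rate
per unordered state pair). Symmetry forces the uniform stationary
distribution, which is used as the root prior.

The likelihood is Felsenstein's pruning algorithm with per-node scaling;
transition matrices come from the symmetric eigendecomposition of the
generator. Rates are fitted by bounded multi-start optimisation of the
log-likelihood over log-rates (bounds 10^-8^ to 10^3^ per unit branch
length, five starts drawn log-uniformly under a fixed seed). Character
histories are sampled exactly: the root state from its posterior, each
child state backward from `P(t)[parent, ·] × partial(child)`, and the
within-branch path by uniformization conditional on the endpoints.
Uniformization rather than rejection sampling was chosen because it is
seed-reproducible with bounded runtime at any rate magnitude while drawing
from the identical conditional distribution. The default of 1,000 sampled
histories is the conventional sample size for summarising mapping
uncertainty; ancestral summaries are empirical state frequencies per
internal node, addressed through an MRCA lookup. Polytomies are accepted
as multifurcations throughout.

The packaged panel tree (`brown_support_tree_synthetic()`) is a synthetic
stand-in with a plausible topology for the seven profiled brown algal
species, shipped so the mapping stage runs end to end without downloads;
conclusions about real ancestral nodes require a real marker-gene tree and
the full profiling compendium, neither of which is bundled.

## Synthetic data: what passing tests do and do not show

The generators produce inputs with the statistical structure each stage
assumes, holding the ground truth:

* `gen_knowledge_base()` grows a random pathway over the steroid grammar
  (desaturations, reductions, alkylations, hydroxylations at fixed
  positions) and hides a configurable fraction of intermediates. Because
  successive operations often commute, a hidden intermediate is recoverable
  as a structure, but the chosen chain may route a tying order-isomer; the
  recovery metric counts structural regeneration.
* `gen_peak_tables()` emulates the linear detector response
  `area = RRF · mass · (area_IS/IS_amount) · (1 + ε)`, `ε ~ N(0, σ)`
  truncated to keep areas positive, with peaks placed at the standards'
  retention indices on a synthetic ladder and two noise-free calibration
  mixes. Synthetic spectra are distinct fingerprints, not library-quality
  reference spectra.
* `gen_tree_characters()` simulates a Yule tree rescaled to unit height and
  evolves tip states by exact CTMC transition sampling from a uniform root.

Passing tests on these inputs demonstrate that the pipeline inverts its own
generative model to numerical precision, that the estimators degrade
gracefully with noise, and that the samplers agree with exact enumeration
on small instances. They do not demonstrate robustness to co-eluting peaks,
detector saturation, retention drift, model misspecification of the CTMC,
or incomplete transformation libraries on real data.

## Numerical choices and problem sizes

Diffs, libraries and edges are kept in canonical sorted order, so equal
inputs give byte-identical outputs. Exhaustive checks in the test suite run
the deduction and chain-selection oracles on 500 random knowledge bases of
at most 8 molecules, the pruning likelihood against full state enumeration
on trees of up to 6 tips (agreement to 10^-10^), sampled ancestral
frequencies against analytic marginal posteriors with 10,000 histories, and
rate recovery as the median over 200 simulated 64-tip trees — sizes chosen
so the whole suite completes in a few minutes on one core while still
exercising every code path exactly.

## Known limitations

* No stereochemistry beyond the epimer-proxy aliasing; NMR-level epimer
  distinction is out of scope.
* The packaged reference model is a reconstruction at the granularity of
  the observable panel; early 24-alkylated intermediates are deliberately
  absent, and the mozukulin structures are synthetic stand-ins.
* Raw chromatogram processing (peak picking, deconvolution, mzML) is out of
  scope; the profiling stage starts from integrated peak tables.
* The SYM model has no rate heterogeneity or hidden states; support states
  are treated as error-free observations at the tips.
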