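---
title: "Methods: phylogenetic patterns in use guilds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic patterns in use guilds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the models and their assumptions, the tunable parameters and defaults,
the numerical choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## The setting

The unit of analysis is a *guild*: a set of species sharing a binary use
or management flag (edible, condiment, wrapping; wild, cultivated; nine
organ flags) on a dated, rooted phylogeny. All statistics are
branch-length-weighted, so the tree must carry a length on every edge —
a missing length is an error, never defaulted to 1. Name matching is done
on canonical underscore binomials (`canonicalize_name()`),
case-sensitively, matching the labeling convention of dated megatrees.

## Building the study tree

`graft_species()` follows the crown-node placement rule: a species absent
from the megatree is attached as a new child of the most recent common
ancestor of its congeners (a monotypic genus attaches at its single tip's
parent), or of its family's tips when the genus is absent. The pendant
edge equals the attachment node's age, the only choice that keeps the
tree ultrametric without inventing stem ages; it also means grafts create
polytomies, so every downstream statistic accepts polytomies natively.
Species whose genus and family are both unrepresented are reported in the
graft report and dropped rather than failing the run — the analysis
proceeds with the placeable subset. Genus membership of megatree tips is
read from tip labels; family membership needs a user-supplied tip-family
map, because megatree labels carry genus but not family. Age
interpolation for undated nodes and stem-age attachment variants are out
of scope: the input megatree is assumed fully dated (checked with a
relative ultrametricity tolerance, default `1e-6`).

## Fritz–Purvis D

The dispersion kernel *d* works tips-to-root: each internal node receives
the weighted mean of its children's values, with weights equal to inverse
child-edge lengths (equal weights where a zero-length edge occurs), and
contributes the summed absolute deviation of its children from that mean.
For a bifurcation this reduces to |left − right| for *any* weights, so
the polytomy formula is used uniformly. The original method leaves the
nodal estimator to its implementation; any consistent kernel works
because D is re-anchored by two permutation nulls computed with the same
kernel:

* random anchor — the trait shuffled uniformly across tips (mean d
  defines D = 1);
* Brownian anchor — a threshold trait: Brownian motion along the tree
  (root 0, Gaussian increments with variance equal to edge length), then
  1 assigned to exactly the k tips with the largest values, k being the
  observed prevalence (mean d defines D = 0).

Because the same simulator generates both the observed calibration traits
and the null anchor, the 0/1 scale is structural, not tuned: on simulated
trees the mean D of Brownian-threshold traits sits at 0 and of shuffled
traits at 1 up to Monte-Carlo error (the acceptance script recomputes
both). D is invariant under rescaling all branch lengths, symmetric in
trait inversion, and unbounded on both sides — clade-packed guilds
routinely score D < 0 and no clipping is applied. Both nulls default to
1000 permutations. P values use the add-one estimator
`(1 + #extreme)/(n_perm + 1)`, which never returns 0; `p_rand` counts
shuffles at least as clumped as observed (d ≤ d_obs) and `p_brownian`
simulations at least as dispersed (d ≥ d_obs), so both tails of the scale
are reported. A constant trait, or a degenerate tree on which the two
anchors coincide, is an error rather than a silent NA.

## Alpha diversity and its null

PD follows the rooted convention (`include_root = TRUE`): the branch
length of the union of root-to-tip paths, so PD of the full tip set is
exactly the tree length, and PD is monotone under adding species. The
flag is exposed for sensitivity checks; `include_root = FALSE` removes
the shared root-to-MRCA spine. MPD and MNTD are computed from a patristic
distance matrix built once per tree and reused across guilds and null
draws (O(n²) memory, which at a few hundred species is the right trade).

The null draws guilds of the observed size uniformly without replacement
from the full tip pool — the "taxa labels" style null, unweighted because
all guilds are presence/absence. `ses = (obs − mean null)/sd null`;
rank-based p with the add-one estimator, so at 999 draws the nominal mass
below 0.05 is 50/1000. When the null has zero spread (guild = entire
pool) ses is `NA` and p is still a rank. Under its own null the p value
is calibrated: the acceptance suite checks that uniformly drawn guilds
are "significantly clustered" about 5 % of the time.

## Beta diversity

Edges are classified by whether their descendant tips intersect guild A
and/or B, with root paths included for consistency with the PD
convention; the shared/unique lengths (a, b, c) obey
a + b + c = PD(A ∪ B) exactly. Components follow the additive
decomposition: overall dissimilarity `pbd_sor = (b + c)/(2a + b + c)`
(= 1 − PhyloSor), true turnover `pbd_sim = min(b,c)/(a + min(b,c))`, and
the nestedness-resultant remainder `pbd_sne = pbd_sor − pbd_sim`; for
nested guilds min(b, c) = 0 forces pbd_sim = 0. The additivity and
partition identities are enforced to 1e-12 in tests.

The SES null permutes the tree's tip labels wholesale, which redraws both
memberships with sizes *and overlap* held fixed. This choice — the
natural reading of a tip shuffle on a fixed membership table — preserves
the set-theoretic geometry of the comparison so the SES isolates
phylogenetic placement rather than list overlap. Flags are two-sided at
|ses| > 1.96. One degenerate corner follows from the fixed-overlap
design: for identical guilds every null replicate also has all components
zero, so the null sd is 0 and ses is reported `NA` (flagged false) rather
than a pseudo-extreme value.

## Hot nodes

One tip shuffle yields enrichment counts for *all* nodes simultaneously
(a full null scan per permutation); per node,
`ses = (count − null mean)/null sd` from the permutation moments. The
marginal null at a clade of m tips is hypergeometric — m draws from k
positives among n tips — and the test suite uses its closed-form mean and
sd as an analytic oracle; the scan itself stays permutation-based so all
nodes share one exchangeable null. Only clades with at least
`min_clade = 10` tips are evaluated (smaller lineages give unstable
permutation moments); filtered clades are absent from the output, not
present-but-unflagged. Flagging is one-sided (enrichment only) at
ses > 1.96; under a shuffled trait the realized false-flag rate sits at
the threshold's upper-tail mass (~0.025, discreteness-dependent). Nested
hot clades are all reported; `maximal_hot_nodes()` collapses to the
outermost ones. `annotate_tree()` writes `HOT|ses=...` node labels into a
Newick as a text stand-in for shaded-clade figures, and refuses stale
results via clade signatures.

## The synthetic-data generator

Trees are pure-birth (Yule): ultrametric by construction without
extinction pruning, with enough shape variation for calibration tests;
they are rescaled to unit depth, so all reported distances are fractions
of tree depth. Taxonomies are clade-respecting partitions (families are
monophyletic tip blocks, genera subdivide them), so genus and family
crown nodes are well-defined and the grafting rule is exercised exactly.
Guilds are realized at their requested sizes exactly, in one of three
modes: uniform draws, Brownian-threshold draws, or clade-planting —
filling the guild from the largest whole clades that fit, trimming the
last clade's overflow at random, which keeps planted signal interpretable
for power tests.

`make_study_like_dataset()` fixes the study conditions: 473 tips, guild
sizes 437/51/26/55/416 (edible/condiment/wrapping/cultivated/wild), 320
genera in 96 families (field-realistic for a regional flora of this
size), condiment clade-planted, wrapping clade-planted in lineages
disjoint from condiment (so their comparison is turnover-dominated),
cultivated clade-planted, wild uniform. Two arithmetic facts shape the
overlap design. First, every species must carry at least one use flag,
but the edible guild (437) is smaller than the flora (473): the generator
therefore assigns edible to every species holding no other use flag and
tops it up to 437 with the highest Brownian scores among
condiment/wrapping members — condiment and wrapping end up mostly, but
not fully, nested in edible. Second, wild (416) plus cultivated (55)
cannot cover 473 species, so the two management flags are drawn
independently and may overlap, with no coverage guarantee. Organ flags
are independent Bernoulli draws at field-plausible prevalences (fruits
0.35 down to wood 0.02); correlation structure among organs is
deliberately not modeled.

What passing tests on this generator do and do not show: they demonstrate
that each statistic recovers the structure the generator plants (clade
enrichment, nesting, turnover, Brownian signal) and is calibrated under
its own null — they do not certify behaviour on real floras, where guild
membership correlates with taxonomy in ways no planting scheme mimics,
trees contain soft polytomies from megatree grafting at much higher
rates, and sampling of the species pool is itself non-random.

## Seeds and determinism

Every stochastic function takes an explicit seed; pipeline stages derive
child seeds from one master seed by a fixed string-hash splitting rule
(`derive_seed()`), so adding or reordering a stage never shifts another
stage's draws, and one master seed reproduces an entire synthetic dataset
and pipeline run bit-for-bit. Guild-level child seeds are keyed by the
guild's *membership*, not its name, so two identically composed guilds
produce identical rows.

## Problem sizes

The default analysis constants are 1000 permutations per D statistic, 999
null draws per SES, clade floor 10 and flag threshold 1.96. The package's
own verification runs use a 300-tip tree with 200 replicate traits at
1000 permutations for the D-scale anchors, 500 replicates at 199 nulls
for p-value calibration, and 100 seeds for the power checks — sizes at
which a full verification pass completes in minutes on a single core
while keeping Monte-Carlo error well inside the asserted bands.

## Known limitations

* Nomenclature is validated, never resolved: synonym merging against a
  taxonomic backbone must happen upstream.
* The megatree module implements crown-node grafting only; stem-age
  attachment and age interpolation for undated trees are out of scope.
* The D kernel's nodal weighting (inverse edge lengths) is one of several
  consistent choices; cross-implementation comparisons of raw d values
  are approximate even though the D scale itself is anchor-stable.
* Alpha/beta nulls are unweighted tip-pool/tip-shuffle models; abundance
  weighting and alternative community nulls are not provided.
* All statistics are presence/absence on a single tree; phylogenetic
  uncertainty (tree sets, posterior samples) is not propagated.
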