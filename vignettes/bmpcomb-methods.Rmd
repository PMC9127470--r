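---
title: "Methods: quantifying combinatorial BMP ligand interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying combinatorial BMP ligand interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmpcomb)
```

# Overview

Bone Morphogenetic Protein (BMP) ligands signal through shared pools of
Type I and Type II receptor subunits. Because roughly ten homodimeric
ligands compete promiscuously for the same receptors, the response to a
ligand *pair* is not predictable from the two individual responses: pairs
can be additive, antagonistic, suppressive (below both individual
responses) or synergistic, and the same pair can switch type when the
receptor profile of the receiving cell changes. `bmpcomb` implements a
complete analysis chain for pairwise-titration reporter screens of this
kind:

1. a synthetic screen generator that emulates the experiment design and
   produces ground-truth-labelled data from a mechanistic model,
2. preprocessing (cell-count filtering, background subtraction, plate and
   replicate harmonization),
3. single-ligand dose-response summaries (Hill fits, Relative Ligand
   Strength),
4. the Interaction Coefficient scale with replicate-noise gating,
5. hierarchical equivalence-group clustering with a monochromaticity rule,
   and an optional sequence-similarity comparison,
6. a competitive trimeric-complex equilibrium model with multi-start
   bounded least-squares parameter inference.

Everything runs on synthetic data; no external download is required.

# The screen design

Each of the N panel ligands appears as a single-ligand gradient, as a
"self-pair" (the ligand combined with itself, the saturated-additivity
control), and in all `choose(N, 2)` unordered pairs: `2N + N(N-1)/2`
condition rows (65 for N = 10). Each row holds a no-ligand control plus
nine dose pairs produced by a trapezoid sweep (`ratio_concentrations()`):
ligand A stays at its top (near-saturating) dose while B climbs a
geometric ladder, then B stays at top while A descends the mirrored
ladder, so at least one ligand is near saturation at every ratio and the
center ratio has both at top dose. The sweep is symmetric under exchanging
the two ligands, which is what lets the analysis read a pair's individual
references off the two gradient rows: the B-side dose at ratio $t$ equals
the gradient dose at the mirrored index $n + 1 - t$.

Per-ligand top concentrations and dilution folds are free parameters of
`ligand_panel()`. As in real screens, the packaged defaults use a steeper
ladder (fold 3) for strong activators and a shallower one (fold 2) for
weak ligands, whose interactions would otherwise be sampled mostly at
doses too low to gate reliably.

One bookkeeping note: 65 rows of nine ratios plus one control give 650
wells per biological replicate; accounts of comparable screens sometimes
quote slightly larger totals including extra control wells whose
composition is not specified, and the generator follows the 65 x 10
arithmetic exactly.

# The measurement model

The generator turns noiseless model output $S$ into a well median
fluorescence as

$$\mathrm{YFP} = f_{\mathrm{plate}} \cdot f_{\mathrm{rep}} \cdot
  (g\,S + b) \cdot \varepsilon,\qquad
  \varepsilon \sim \mathrm{LogNormal}(-\sigma^2/2, \sigma),$$

with a per-plate factor (uniform in [0.8, 1.2], emulating staggered
incubation times of 20-24 h under linear reporter accumulation), a
per-replicate factor (uniform in [0.7, 1.3]), gain $g$ (default 1000 a.u.
per model unit), additive background $b$ (mean 50 a.u., spread 5), and
mean-one lognormal per-well noise with CV $\sigma \approx$ 10% by default.
Cell counts are Poisson (mean 3000) with a small fraction (2%) of
low-count failures below the 500-cell filter. Condition rows are assigned
to plates six at a time, the assignment reshuffled per biological
replicate as in the robotic protocol; a no-ligand control and a reference
condition in quadruplicate are placed on every plate so that plate
rescaling is identifiable even when an individual well drops out. The
generator does not emulate per-cell fluorescence distributions, cytometry
event files, or robot scheduling; per-well medians are the starting point.

# Preprocessing

`filter_and_subtract()` drops wells with fewer than 500 cells (wells with
exactly 500 are retained) and subtracts, from every well, the median of
its plate's zero-dose control wells. The per-plate background (rather
than a global one) is the package default because it is robust to a
single bad control well. Negative post-subtraction values are retained
through rescaling and clipped to zero only where the Interaction
Coefficient requires nonnegative responses; clipping earlier would bias
the least-squares rescaling. `rescale_plates()` multiplies each plate by
the closed-form factor $\alpha = \sum x_{\mathrm{ref}} x / \sum x^2$
minimizing the squared error against the reference plate over shared
technical-replicate conditions, and `rescale_replicates()` applies the
same one-parameter alignment between biological replicates over all
shared conditions. Both default to the reference with the most shared
conditions (ties to the lowest identifier), keep per-replicate values
(no averaging), and are exactly idempotent.

# Dose-response summaries

Gradients are fitted with a three-parameter Hill function
$y = y_{max} c^n / (EC_{50}^n + c^n)$ with the baseline fixed at zero
(responses are background subtracted), all replicates fitted jointly by
total least squares. $y_{max}$ is profiled out in closed form, and the
remaining two parameters are minimized from a deterministic 3 x 3 grid of
starts under bounds $n \in [0.1, 10]$ and
$EC_{50} \in [\min c / 100, \max c \times 100]$, so the fit has no
randomness. Ligands whose responses never rise above zero are flagged
non-activators with $y_{max} = 0$ rather than failing.

Relative Ligand Strength (RLS) is the median top-dose response of a
ligand divided by the largest such median in the panel. The measured
top-dose median is used rather than the fitted plateau so that ligands
that fail to saturate still receive a defined RLS; for a strongly
non-saturating ligand the two can diverge, which is the reason the
package reports both.

# The Interaction Coefficient

For a pair measured at one ratio, let $f(A) \le f(B)$ be the two
individual responses (read from the gradient rows at the matching doses)
and $f(A{+}B)$ the combined response. The IC is

$$IC = \begin{cases}
 f(A{+}B) / (f(A) + f(B)) & f(A{+}B) \ge f(A)+f(B) \\
 f(A{+}B)/f(B) - 1        & f(A) \le f(A{+}B) < f(A)+f(B) \\
 f(A{+}B)/f(A) - 2        & f(A{+}B) < f(A).
\end{cases}$$

IC = 0 is saturated additivity (the combination equals the stronger
individual; the null for a self-pair at saturation), IC = 1 is linear
additivity, (0, 1) additive, [-1, 0) antagonistic, below -1 suppressive,
above 1 synergistic. The scale is bounded below by -2 and unbounded
above, invariant to a global rescaling of all responses, and independent
of which ligand is labelled A. The boundary case $f(A{+}B) = f(A)$ is
assigned to the middle branch so that an all-equal self-pair yields
exactly 0.

**Gating.** Medians of three or four biological replicates are noisy, so
a nonzero IC is reported only when the replicate *ranges* separate: the
combination range must be disjoint from the stronger individual's range
by more than a threshold $\theta$ equal to the context's maximum
background-subtracted response divided by 30 (about 3% of dynamic range).
A synergy claim must additionally separate from the range of
replicate-paired sums $f(A)_i + f(B)_i$ (pairing by replicate index is
the package's choice of how to form the sum's range), and a suppression
claim from the weaker individual's range. When only the weaker claim is
supported, the IC is recomputed against the supported regime's boundary
($f(A{+}B)/f(B) - 1$, clamped to $[-1, 1]$) rather than discarded. A
pair's summary IC is the gated value of largest magnitude across ratios;
exact magnitude ties break toward the ratio nearest 1:1 and then toward
the negative value, and a manual-override table (context, pair, forced
value or category) can replace individual summaries, with the override
flagged, mirroring how borderline rims are handled in practice. The
weak/strong antagonism annotation splits at |IC| = 0.5; this is an
adjustable display convention, not a category boundary.

# Equivalence groups

Each ligand in each context is summarized by N + 1 features: its summary
IC with the N - 1 other ligands, its self-pair IC, and twice its RLS. The
doubling makes a 0.5 difference in RLS contribute a Euclidean distance of
1 -- the same as a whole-regime difference in one IC -- so a single cut
threshold of 1 is meaningful for both. Ligands are clustered by
complete-linkage agglomeration on Euclidean distances and groups merge
only while the linkage is strictly below the threshold, so a pure
boundary difference separates. Groups are then made *monochromatic*: if
two members disagree in their interaction category with any outside
ligand, the group is split top-down along its linkage subtree until every
group is internally consistent. (For complete linkage, re-clustering a
clade equals the original tree restricted to it, which is what the
splitting uses.)

For the global analysis the per-context feature blocks are concatenated
(7 contexts x 11 features = 77 for the full design) and the tree is cut
at a Euclidean distance of 7; monochromaticity is deliberately not
enforced globally, since with many contexts a single discordant pairwise
call should not split a group. A sevenfold increase of the squared
distance would instead give a cut of sqrt(7); the package follows the
literal Euclidean reading by default and exposes the threshold so either
convention can be used.

Sequence comparison (`sequence_distance_matrix()`) scores every pair of
aligned ligand sequences over the columns with no gap in any sequence
using BLOSUM50, normalizes $d_{ij} = 1 - s_{ij} / \min(s_{ii}, s_{jj})$
(the normalization is the package's own definition; it makes identical
sequences distance 0 and anchors each pair against its weaker
self-score), and clusters with average linkage. Unequal-length input is
aligned with the external `mafft` aligner when available; equal-width
input is taken as already aligned. `correlate_profiles()` reports the
Pearson correlation between sequence distances and interaction-feature
distances over ligand pairs, per context, globally, and over seeded
random context subsets.

# The competitive equilibrium model

The mechanistic core treats a signaling complex as one ligand $L_i$, one
Type I receptor $A_j$ and one Type II receptor $B_k$ (a deliberate
trimeric simplification of the tetrameric complex), formed with affinity
$K_{ijk}$ and phosphorylating SMAD1/5/8 with activity $\epsilon_{ijk}$:

$$T_{ijk} = K_{ijk} L_i^0 A_j B_k, \qquad
  A_j + \sum_{ik} T_{ijk} = A_j^0, \qquad
  B_k + \sum_{ij} T_{ijk} = B_k^0, \qquad
  S = \sum_{ijk} \epsilon_{ijk} T_{ijk},$$

with ligand concentrations held constant (reservoir assumption) and
binding assumed fast relative to downstream activation. Co-receptors,
secreted inhibitors, inhibitory SMADs and receptor turnover are outside
the model's scope. The steady state is found by damped fixed-point
iteration on the free receptor concentrations,
$a_j \leftarrow A_j^0 / (1 + \sum_{ik} K_{ijk} L_i^0 b_k)$ and the
symmetric update for $b_k$, iterated to a relative change below 1e-12
(damping 0.5 engages only when the relaxation oscillates; a Newton
fallback with analytic Jacobian catches the rare non-converged
environment). The batch form solves hundreds of ligand environments in
one call, which is what makes simulation and fitting cheap. An
independent oracle (`steady_state_oracle()`) integrates the mass-action
kinetics $dT_{ijk}/dt = k_{off}(K_{ijk} L_i^0 a_j b_k - T_{ijk})$ with a
stiff ODE integrator and shares no code with the fixed-point path; the
two agree to 1e-6 relative on randomized instances in the test suite.
Uniqueness of the equilibrium is assumed from the monotone relaxation
structure rather than proven; any disagreement between the two solvers
would surface in those tests.

`complex_output_decomposition()` reports each complex's share of total
complex abundance and of total output; anti-correlated affinity and
activity shows up as a minority of complexes carrying most of the output.
`ligand_output_attribution()` attributes output to ligands
($\sum_{jk}\epsilon_{ijk}T_{ijk}$) and Type I receptors, and reports
percent changes between single-ligand and paired environments or between
receptor contexts -- the quantitative face of the redistribution
arguments below.

## The toy model

`toy_model_factory()` packages a 3-ligand x 2 Type I x 2 Type II instance
whose numeric values are the package's own (chosen by constrained search;
they are not published constants) and which reproduces three signature
behaviors by construction: (i) knocking down the black Type I receptor
reduces the pink ligand's output even though pink signals through a
complex that does not contain the perturbed receptor -- the freed black
Type II subunits pull white Type I receptors into a silent complex; (ii)
gold, a strong but weakly-active binder of pink's signaling complex,
suppresses pink (the pair signals below both individuals); and (iii) pink
and blue are saturated additive in the wild type but antagonistic in the
knockdown, where sequestered pink limits blue. In the search that fixed
the constants, satisfying all three properties together with the
"least-abundant complex carries the most output" pattern required pink's
two silent complexes to have comparably strong affinities rather than a
strong/intermediate split; the packaged values use dose 10, a 20-fold
knockdown, and affinities spanning 0.1-20.

## Packaged synthetic truths

`example_screen_truth()` (10 ligands, 2 Type I x 3 Type II, wild-type and
Type-I-knockdown contexts) embeds the toy motifs in a full panel: a
"pink" family of strong activators signaling through their least-favored
complex, a robust activator family on a separate Type II receptor, a
sequestered weak ligand whose silent sink both suppresses the robust
activators and is the handle for synergy, a silent super-binder that
releases the pink family onto its active complex, a "gold" suppressor,
and non-activating antagonists. The parameter values were chosen so that
every planted nonzero interaction clears the replicate-noise gate with a
wide margin at the generator's default noise, and every planted null
falls below the gate even at zero noise -- the planted structure is
deliberately placed away from category boundaries, because a truth
sitting on a boundary is unrecoverable from noisy data by any method.
`example_fit_truth()` is the 5-ligand (one per archetype) x 2 Type I x 3
Type II x 4-context version used for fit-recovery experiments.

# Parameter fitting

`assemble_observations()` collapses a processed screen to per-condition
medians, normalizes responses and receptor expressions to a maximum of 1
(the normalization only fixes units; the free activities absorb any
global scale), and `fit_multistart()` minimizes
$\sum(\mathrm{observed} - S_{\mathrm{model}})^2$ by Levenberg-Marquardt
in log-parameter space with $K, \epsilon \in [10^{-4}, 10^2]$ and
per-receptor expression rescalings $\rho \in [1/3, 3]$ (absorbing
quantification uncertainty in the expression estimates). The objective is
strongly multimodal, and three inexpensive structural stages make random
starts competitive. First, the activities, which enter the output
linearly once the binding equilibrium is solved, are initialized at their
non-negative least-squares optimum given the drawn affinities (variable
projection). Second, each ligand's affinity/activity block is pre-fitted
against that ligand's own single-ligand rows -- the hierarchical order in
which a practitioner would fit by hand, and the stage that contributes
most: single-ligand dose-responses pin each ligand's binding scale before
the pair data have to resolve competition. Third, every start's coarse
joint descent is interrupted once to re-profile the activities (a move
that hops out of activity-miscalibrated basins), and the best few starts
are polished to convergence with the same alternation. Plain log-uniform
multistart without these stages stalls well short of the optimum on the
packaged truths. The default run uses 50 starts; production-scale
analyses of real screens use orders of magnitude more, and the
non-identifiability that motivates filtering (a weak ligand's weakness
can come from low affinity or low activity) is expected and documented
rather than fought.

Even with these stages the objective's multimodality is a real
limitation. On the packaged noiseless truth, a default-sized multistart
reliably reaches fits whose predicted responses are essentially
indistinguishable from the data in aggregate (response-space R^2 above
0.999) and that reproduce every planted non-additive interaction, yet
such fits can still mis-assign which receptor carries a silent
sequestration complex -- a discrete topology error that survives because
its response-space cost is concentrated in a handful of
weak-signal conditions. Escaping such basins requires orders of
magnitude more starts than a default-sized run; production analyses of real
screens have used thousands. This is the same non-identifiability that
motivates qualitative solution filtering in the first place, and the
recovery report is designed to expose it rather than hide it.

`filter_solutions()` keeps fits that reproduce required interaction
categories on named hard pairs -- the suppressive and synergistic pairs,
predicted by running the same IC-and-gating machinery on each fit's
noiseless predictions -- within a residual cap (default twice the best
residual). The per-criterion thresholds used with real data are
data-specific, so the packaged defaults are category-match requirements
plus the residual cap, and `evaluate_recovery()` reports response-space
R^2, the fraction of the truth's summary categories reproduced, and the
correlation between log-affinity and log-activity across complexes.

# What the synthetic tests do and do not show

The generator emulates the design, the corrective structure of the noise
(plate and replicate factors, background, lognormal well noise, dropped
wells), and mechanistically-grounded ground truth. It does not emulate
ligand lot variability, cross-well contamination, cytometry gating
artifacts, receptor expression drift, or any real ligand's biochemistry.
Passing the planted-truth recovery tests therefore demonstrates that the
pipeline's inference is correct and noise-robust under its stated noise
model -- not that any particular biological conclusion about real BMP
ligands is reproduced. Problem sizes in the test suite (a 10-ligand,
2-context screen at 4 replicates for recovery; a 5-ligand, 4-context,
50-start run for fitting) were chosen as the smallest instances that
exercise every code path meaningfully.

# Numerical choices

* Equilibrium solver: relative tolerance 1e-12, iteration cap 1e5,
  damping 0.5 on oscillation, Newton fallback; batch solves reuse the
  previous solution as a warm start inside fitting.
* Hill fits: deterministic 3 x 3 start grid, L-BFGS-B, profiled maximum.
* Gating: theta = context maximum / 30; replicate ranges are plain
  min/max (no outlier trimming -- that is what the override table is
  for).
* Clustering: strict-inequality merge at the cut; monochromatic splitting
  recurses top-down on the linkage tree.
* Degenerate inputs: an all-zero pair response is flagged degenerate with
  IC 0; a zero-output state flags output shares as undefined; fewer than
  two replicates cannot support any interaction claim and gate to 0 with
  a warning.
* Determinism: every stochastic step (generation, start draws, subset
  sampling) takes an explicit integer seed, and identical configurations
  reproduce byte-identical artifacts.
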