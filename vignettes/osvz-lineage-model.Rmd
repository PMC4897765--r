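---
title: "Modeling the critical window for OSVZ formation: lineage simulation, division-mode inference and temporal expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the critical window for OSVZ formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osvzlineage)
```

## The biological model

In gyrencephalic species such as the ferret, the outer subventricular zone
(OSVZ) is a second major germinal layer of the developing cortex, rich in
basal radial glia cells (bRGCs). `osvzlineage` implements a quantitative
account of how that layer forms: apical radial glia cells (aRGCs) of the
ventricular zone (VZ) pass through a brief embryonic window — opened by
falling *Cdh1* expression around E34 and closed by rising *Trnp1* around
birth (E42/P0) — during which they switch from self-renewing divisions to
self-consuming, bRGC-generating divisions. The bRGCs born in that window
migrate through the inner SVZ (ISVZ) and found the OSVZ; afterwards the OSVZ
sustains itself exclusively by local bRGC self-amplification, while the VZ
keeps feeding bRGCs only to the ISVZ.

The package has three computational layers:

1. a stochastic branching-process **simulator** of clonal lineages with the
   gene-gated fate rules, migration delays, retroviral and BrdU labeling;
2. an **inference** layer that inverts labeled-cell censuses and
   cleavage-angle samples into division-mode estimates and delamination
   predictions;
3. a three-stage **expression screen** (permutation ANOVA, temporal-profile
   classification, comparative-Ct fold changes).

A fourth layer of synthetic-data generators emulates every input the
pipeline consumes, so all stages are testable in closed loop without any
external data.

All clocks run on real-valued embryonic days; postnatal day $n$ is
$E(42+n)$ (`to_embryonic_day()`). Fractional ages such as E36.5 are valid —
the BrdU design needs them.

## The branching process

Each cell divides exactly once, one cell-cycle after its birth, into two
daughters drawn from the fate rule in force at the division time. The event
queue is keyed by division times, so a run is a frontier-by-frontier sweep
over generations.

* **Cell cycle.** Only S-phase (about 12 h) is observationally constrained;
  total cycle length is a free parameter, defaulting to 24 h for every
  cycling type (aRGC, bRGC, IPC). Absolute durations only rescale the
  clock. Migrating/differentiating neurons and star cells never divide.
* **The gene gate.** The qualitative Cdh1/Trnp1 state machine has three
  states: `pre` (Cdh1 HIGH: self-renewal enforced), `open` (both LOW: the
  critical window; self-consuming, bRGC-generating divisions) and `closed`
  (Trnp1 HIGH: renewal with ISVZ-destined bRGC output). Cdh1 HIGH
  dominates. The default track switches Cdh1 at E34 and Trnp1 at E42. No
  quantitative dose-response is known, so only this qualitative gate is
  modeled; `gene_level_track()` lets either breakpoint be moved (or pinned,
  reproducing the overexpression experiments).
* **Fate distributions.** `default_fate_rules()` is a configuration preset,
  loosely calibrated so that short-survival labeled fractions resemble the
  observed developmental series (about half aRGCs before and after the
  window, a burst of bRGC production with ~24% aRGC retention inside it).
  These probabilities are *inputs* to the simulator; no test or result
  asserts them as outputs. The open state is split at E36 into a burst and
  a moderate sub-regime, since the strongly self-consuming phase lasts only
  about two days. `mode_rule_set(mode_fractions(p, q, r))` builds the
  homogeneous one-round rule sets used for analytic checks.
* **No apoptosis** by default (nothing constrains it); the rule-set
  interface accepts arbitrary outcome tables if death-like regimes are
  needed.

### Migration as a lineage stream

Newborn basal progenitors take about 2 days to reach the ISVZ and 2 more to
reach the OSVZ — longer than a cell cycle. No individual cell survives its
own journey, so migration is modeled as a property of the basal
*sub-lineage*: a stream leaving the VZ at time $t_0$ occupies the ISVZ from
$t_0 + d_1$ and the OSVZ from $t_0 + d_1 + d_2$, and daughters born while
the journey is pending inherit the stream. A stream advances to the OSVZ
only if its origin time and its arrival time both fall inside the entry
window (default $[E34, E42]$) *and* the gene gate was open at its origin —
OSVZ competence is conferred at birth. This is what makes the
window-closure experiment work: pinning Trnp1 HIGH from E34 leaves the ISVZ
populated but the OSVZ empty of labeled bRGCs at P0.

Whether the few mid-window OSVZ bRGCs arriving between E36 and E38 come
directly from the VZ or from an extra ISVZ division is observationally
open. Both routes are implemented; `migration_rules(allow_isvz_route =
FALSE)` (the default) uses the direct route only, because letting every
in-window ISVZ resident re-enter the stream drains the ISVZ, contradicting
its observed persistent bRGC richness.

### Labeling semantics

* **Retroviral reporter.** A ventricular injection can transduce only
  apically attached cells; local ISVZ/OSVZ injections reach somata in the
  layer plus, with retrograde labeling, apical-layer cells whose basal
  process spans the site. Transduction sets an `EPISOMAL` state; at the
  first division afterwards the reporter integrates into exactly one
  uniformly chosen daughter (`INTEGRATED`), which transmits it to all
  descendants. Infected cells that never divide are invisible to
  integrated-reporter censuses — retroviral reporters require division.
* **BrdU.** A pulse marks every cell whose S-phase interval (the 12 h
  window ending at its division) overlaps the administration interval, and
  the label is heritable; dilution is not modeled.

## Division-mode inference

With single-daughter integration, one division round maps the mode mixture
$(p, q, r)$ — symmetric self-amplifying, asymmetric, symmetric
self-consuming — onto the expected labeled mother-type fraction

$$L = p + q/2,$$

with the boundary cases $L = 1, 0.5, 0$ for the three homogeneous regimes.
The inversion is under-determined: for observed $L$, the feasible set is
the one-parameter family $p = L - q/2$, $r = 1 - L - q/2$ with
$q \in [0, \min(2L, 2(1-L))]$, collapsing to a unique point at $L \in
\{0, 1\}$ or when $q$ is known (`feasible_mode_fractions()`). "One round"
means every labeled founder divides exactly once — the short-survival
(2-day) reading; multi-round censuses are a matter for the simulator, not
the closed form.

The population fate call (>50% amplification, 50% renewal, <50%
consumption) is made by a two-sided exact binomial test against 0.5
(default $\alpha = 0.05$), because the literal point rule would classify
any finite-sample fraction other than exactly one half; renewal as a point
hypothesis is a measure-zero event. The literal rule remains available
(`method = "threshold"`), and reported intervals are Wilson score intervals
(well behaved at extreme fractions) alongside the exact test's interval.

Cleavage planes are classed horizontal $[0°, 30°)$, oblique $[30°, 60°)$,
vertical $[60°, 90°]$ against the ventricular surface; measurements against
the radial-fiber scaffold are the complement, and the radial rule is
*defined* by conversion so the two conventions agree exactly, including at
the 30°/60° boundaries (assigned upward; the boundary rule is a convention
choice — the data never sit exactly on it). Every angle record carries its
convention explicitly. The delamination arithmetic assumes one
delaminating daughter per non-vertical division and none per vertical
division, so a non-vertical mitosis fraction $f$ predicts $d = f/2$
delaminating daughters — at the window's peak, $f = 0.5$ explains only 25%
of daughters leaving the VZ, which is the quantitative argument that
cleavage-plane reorientation alone cannot account for the observed basal
output.

```{r inference-example}
expected_labeled_mother_fraction(mode_fractions(0.5, 0.5, 0))
classify_population_fate(24, 100)
predicted_delamination_fraction(0.5)
```

## The expression screen

Differential expression across the three VZ stages (E30, E34, P1) is tested
per gene with a one-way permutation ANOVA: $p = (1 + \#\{F^{perm} \ge
F^{obs}\}) / (1 + n_{perm})$, 500 permutations by default. One global
relabeling of samples is shared by all genes per draw, preserving gene-gene
correlation; runs are deterministic given a seed. Constant genes get
$p = 1$ by convention. Multiplicity correction defaults to Bonferroni with
Benjamini-Hochberg behind a flag — the procedure description being
reproduced says "Bonferroni false discovery correction", which conflates a
FWER method with FDR control; we implement the named method literally and
expose the standard FDR alternative, logging which was used.

Fold changes are computed on the linear scale from mean log2 intensities,
$FC = 2^{\Delta \bar{x}}$; the early contrast is stage2 vs stage1, the late
contrast stage3 vs stage2. Profiles are classified by the two-contrast
rule (`classify_temporal_profile()`): significant opposite changes give
PEAK/TROUGH, same-direction changes are discarded as monotone, single-phase
changes are EARLY_*/LATE_*, the rest FLAT, with thresholds $FC > 2$ and
adjusted $p < 0.05$.

**Permutation granularity matters.** With 3 replicates per stage there are
only $9!/(3!)^3 = 1{,}680$ distinct relabelings, and relabelings that merely
permute whole groups reproduce the observed statistic, so the smallest
attainable omnibus permutation p-value is about $1/280$ regardless of
$n_{perm}$ — after Bonferroni over more than ~14 genes, *nothing* can be
significant. Two consequences shape the package defaults:

* contrast significance in `profile_screen()` is gated by the omnibus
  ANOVA (a gene must be a DEG overall; each contrast then counts as changed
  when its fold change passes threshold). A per-contrast permutation test
  against the full three-group null is available (`contrast_p =
  "contrast"`) but can never flag monotone genes, whose single-contrast
  difference is dominated by the third group under permutation;
* closed-loop recovery tests use 5 replicates per stage, 100 genes,
  several thousand permutations and BH adjustment — conditions under which
  the planted-truth recovery is exact at zero noise. With triplicates and
  Bonferroni (the literal described procedure) the screen is provably
  unable to call any gene at these scales; the package reproduces the
  procedure but its tests document the regime where it is informative.

qPCR fold changes use the comparative Ct method, $FC = 2^{-\Delta\Delta
C_t}$ with replicate-mean Cts normalized to actin
(`ddct_fold_change()`).

## Synthetic data: what it emulates, and what it does not

`paper_design_library()` catalogues the labeling designs: ventricular
injections at E30-P1 with 2-day survival, long 7-8-day survivals, local
ISVZ/OSVZ injections at P1 followed to P3/P6/P14, and the E34 injection
with a BrdU pulse at E36.0-E36.5 analysed at E38. Sampled-cell counts
default to the reported group sizes (hundreds to ~1,500 cells), so the
statistical behavior of downstream tests is comparable. Census sampling is
without replacement (hypergeometric) from the finite labeled population.
Expression matrices are planted stage means plus i.i.d. Gaussian log2
noise; Ct tables are exact triplicates around known fold changes.

None of the generators model spatial tissue geometry, imaging, probe-level
microarray artifacts, normalization, or clone-to-clone microenvironment
differences. Passing closed-loop tests therefore demonstrates the internal
consistency of the pipeline — simulation, labeling arithmetic, estimators
and screens agree with their own generative assumptions — not that those
assumptions exhaust real histological data.

## Numerical choices and problem sizes

* Determinism: every stochastic entry point takes a seed; a simulation
  configuration *requires* one, and file commands refuse configs without
  one. Identical configurations give bit-identical censuses.
* Sub-stage seeds are derived from the root seed by a fixed affine map kept
  below $2^{31}$.
* Permutation tie handling uses a relative tolerance ($10^{-9}$) so that
  group-relabeling permutations, which reproduce the observed statistic up
  to floating-point summation order, count as ties rather than escapes.
* Degenerate inputs: empty founder sets, censuses outside the simulated
  span, mixed angle conventions, zero expected chi-square counts and
  missing qPCR references are hard errors; over-large sample requests clamp
  with a warning; constant genes get $p = 1$.
* Test problem sizes (chosen to make binomial errors small at desk scale):
  $10^4$ one-round clones for Monte-Carlo/closed-form agreement (3 SE
  $\approx 1.5$ points), 100 seeded replicates for recovery coverage, 1,000
  null genes for type-I calibration, 100-gene planted matrices for profile
  recovery, 20,000 angles for class-fraction convergence.

## Known limitations

* The fate-rule preset is a qualitative calibration, not a fit; the
  experimental percentages it loosely mirrors are observations on animals
  and are not reproduction targets.
* Division-mode inference identifies only $L = p + q/2$; without external
  knowledge of $q$ the mode mixture stays a one-parameter family. No
  Bayesian mixture estimation is attempted.
* The exact-binomial renewal call at $n \approx 100$ has limited power;
  fractions within a few points of 50% are reported as renewal by design.
* A nominal-95% interval covers the truth in almost exactly 95% of
  replicates; empirical coverage over 100 seeds fluctuates by $\pm 2$
  replicates around that expectation.
* Neuronal positioning is schematic (IZ after one day, cortical plate at
  maturation); the model has no 3D geometry.
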