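---
title: "Tracing the FD call combination: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the FD call combination: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdcalls)
```

`fdcalls` reconstructs the evolutionary history of the Parid FD call
combination from annotated recordings and a time-calibrated phylogeny. This
vignette explains the models and criteria the package implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design choices made where more than one defensible option
existed.

## From notes to calls

The raw observational unit is a labelled, timed note (`F`, `D`, or `OTHER`)
inside a recording. Calls are recovered by thresholding silences: a new call
starts when the silence from the previous note's offset exceeds
`gap_threshold` seconds. In Parid recordings the two silence regimes are far
apart — within-call gaps of roughly 0.09 s against between-call gaps of
roughly 2.55 s, with non-overlapping per-species distributions — so any
threshold between the regimes yields the same segmentation.
`estimate_gap_threshold()` finds that gap automatically as the geometric
midpoint of the largest jump in the sorted log-gap sequence; when the gap
distribution is essentially unimodal there is no call structure to find, and
the function returns the maximum gap plus a margin with a warning rather
than inventing a split. Notes with non-positive durations or unsorted onsets
are rejected outright: such records are annotation errors, and silently
"fixing" them would bias segmentation.

Classification is a pure function of the ordered label sequence:

* length 1 → `SINGLE`; all labels identical → `REPEATED`;
* otherwise, if only `F` and `D` occur, run-length encode into homogeneous
  blocks: blocks `F,D` → `FD`, blocks `D,F` → `DF`, three or more blocks →
  `FXD`;
* any mixed call involving `OTHER` → `OTHER_COMBINATION`.

The strict two-block rule is deliberately conservative: FFFDDDFF is *not* an
FD call even though it starts with one. Block lengths never matter. Calls
that mix F or D with other note types could arguably be `FXD`; we place them
in `OTHER_COMBINATION` because the F/D alternation structure is undefined
once a third note class intervenes, and a conservative classifier
underestimates — never overestimates — FD prevalence. The six categories
partition every recording, so category counts always sum to the call count.

The optional `label_notes()` helper assigns F/D from acoustics by a
two-means split on (peak frequency, bandwidth); the higher-frequency cluster
must *also* be the narrower-band one, otherwise all notes are labelled
`OTHER`. Frequency and bandwidth are the two features with stable F/D
differences across Parids, but the primary input path is pre-labelled notes:
automated labelling is a convenience, not a substitute for annotation.

## The FD-consistency criterion

A species scores 1 when at least one recording has at least `min_calls = 5`
calls of which strictly more than `min_prop = 50%` are FD. The criterion
asks for *consistent* use — stable order, and concentrated use within one
recording context — rather than for the existence of any FD call. Both
thresholds are exposed as parameters; the boundaries are inclusive on the
count (5 calls qualify) and strict on the proportion (exactly 50% fails),
and a tie therefore fails. The aggregate FD:DF ratio (`Inf` when no DF
calls occur, `NaN` when neither occurs) is reported as an order-preference
diagnostic but does not enter the verdict: it is an observation about
FD-consistent species, not part of the criterion's definition.

`build_trait_vector()` maps verdicts onto tree tips. Species in the call
data but absent from the tree are dropped with a warning (this mirrors the
practical situation where a recorded species cannot be located in a
synthetic phylogeny); a tip with no call data is an error — the package
never imputes a state.

## The two-state Mk model

FD presence evolves as a continuous-time Markov chain on the tree with gain
rate $q_{01}$ and loss rate $q_{10}$ per Myr. With $s = q_{01} + q_{10}$ the
transition kernel has the closed form

$$P(t) = \frac{1}{s}\begin{pmatrix}
 q_{10} + q_{01}e^{-st} & q_{01}(1-e^{-st}) \\
 q_{10}(1-e^{-st}) & q_{01} + q_{10}e^{-st}
\end{pmatrix},$$

which the implementation uses directly instead of a numerical matrix
exponential (the two agree to near machine precision; the test suite checks
$10^{-12}$). The tip-data likelihood is computed by Felsenstein's pruning
algorithm with per-node rescaling, so trees of hundreds of tips with
strongly asymmetric rates do not underflow. Polytomies are evaluated
natively, and zero-length branches contribute an identity kernel, which
makes the likelihood invariant to resolving polytomies with zero-length
edges — a property the tests exercise.

Assumptions worth keeping in mind: rates are homogeneous across branches and
time; tip states are known without error (the robustness module exists
precisely because this is optimistic); and branch lengths are in Myr, so
rates are per-Myr.

**Root prior.** Two options: `"equal"` (½, ½), the common default in Mk
fitting software, and `"stationary"`
($\pi = (q_{10}, q_{01})/s$). The default is `"equal"`. The choice matters
for the ARD model, where the two priors can shift ancestral probabilities
slightly; both are exposed so either convention can be matched.

**Fitting.** `fit_mk()` maximises the likelihood in log-rate space, bounded
to $[10^{-8}, 10^3]$ per Myr, via `nlminb` from one deterministic start (a
rate of one expected change over the summed branch lengths) plus optional
log-uniform random restarts (default `n_starts = 10`); for ARD the ER
optimum is always added as a start, which guarantees
$\log L_{ARD} \ge \log L_{ER}$ by construction. Monomorphic traits push a
rate to its bound; the fit is returned with `boundary = TRUE` rather than
erroring, because robustness replicates can legitimately produce such data.
Model comparison uses AIC $=-2\log L + 2k$ and BIC
$=-2\log L + k\ln n$ with $n$ = number of tips, the convention under which
$\Delta\mathrm{BIC}-\Delta\mathrm{AIC} = \Delta k(\ln n - 2)$ exactly.

## Marginal ancestral reconstruction

`asr_marginal()` returns, for every internal node, the posterior
probability of each state given all tips and the fitted rates. The default
algorithm is an up–down message pass: one pruning sweep to the root, one
preorder sweep back down, combining each node's below- and above-tree
information. This computes the exact marginal under whatever prior sits at
the root, for any rates, in $O(n)$.

The classical alternative, the rerooting method, treats each internal node
in turn as the root and reads the marginal from the prior times the
conditional likelihoods there (`method = "reroot"`, $O(n^2)$). The two
coincide exactly when the chain is reversible with respect to the root
prior — always for ER with the equal prior, and for ARD with the stationary
prior — because then the pulley principle lets the root move freely. Under
ARD with the equal prior, rerooting is the traditional approximation and
the up–down result is the exact marginal; we default to the exact
computation and keep rerooting available both as a cross-check (the suite
verifies their agreement to $10^{-9}$ in the reversible configurations,
against brute-force enumeration over all ancestral assignments) and for
compatibility with analyses that used it.

`ancestor_probability()` reads $p_1$ at the MRCA of a tip set. A single tip
is rejected: tips are data, not reconstructions.

## Robustness experiments

Three perturbation schemes, each followed by a full ARD refit and
reconstruction per replicate:

* **Recording drop-out** (`p_drop`, default 0.5): every recording is
  independently discarded and FD-consistency is *recomputed* on the
  survivors — not approximated by flipping the trait — because a species
  whose pass rests on many qualifying recordings should be, and is, much
  harder to dislodge. A species losing all recordings scores 0. The survival
  probability of a species with $k$ individually qualifying recordings is
  exactly $1 - p^k$, which the tests verify empirically at 10,000 draws.
* **Species flipping** (`p_flip`, default 0.10): each FD-positive species
  independently loses the trait; negatives never gain it. This models
  over-crediting, the direction the conservative criterion worries about.
* **Single-recording stringency**: deterministic; species passing on exactly
  one qualifying recording are rescored 0.

Replicate refits use the deterministic optimiser starts only, so identical
perturbed traits produce bit-identical results; with `p_drop = 0` or
`p_flip = 0` every replicate reproduces the baseline exactly, and the whole
experiment is a pure function of its seed. The headline summary is the
fraction of simulations in which the focal ancestor's $p_1$ strictly
exceeds `prob_threshold` (default 0.95); strict inequalities are used
throughout, with the thresholds configurable. Replicates with monomorphic
perturbed traits are retained (flagged `boundary`), and outright fit
failures are reported as missing, never dropped silently.

## Synthetic data: what it emulates, and what it does not

`simulate_tree()` wraps `ape::rphylo` (Yule by default) with optional
rescaling to a target root age — 41.3 Myr mimics the depth of a
Paridae-plus-outgroups chronogram. `simulate_trait()` is an exact CTMC
simulation (exponential waiting times along branches) that returns true
internal states and the full event list, so reconstructions can be scored
against truth. `simulate_call_dataset()` generates note-level corpora with
the study's observed scale: 10 recordings per species; calls per recording
negative-binomial with mean 16.5 and SD 14.9 truncated to [2, 148];
within-call silences lognormal with median 0.09 s and between-call silences
with median 2.55 s. The lognormal log-sd is set to 0.4 for both — chosen so
the two silence distributions are disjoint in practice, reflecting the
reported non-overlap, rather than matching the reported (overlapping-range)
standard deviations. F blocks are geometric with mean 2 notes and D blocks
with mean 4; block lengths are arbitrary because the classifier ignores
them, and all of this is configurable. FD-producing species draw 60% of
calls from the FD category; species without the trait have exactly zero
FD/DF/FxD mass.

What passing tests on these corpora show: the segmentation, classification,
consistency, fitting, reconstruction and robustness machinery compose
correctly, recover generating categories and tip traits exactly when the
gap regimes are separated, and recover generating rates within the expected
Monte-Carlo spread. What they do not show: performance under real
annotation noise (overlapping gap regimes, rater disagreement, heterogeneous
per-species FD proportions), none of which the generator models — real
per-species category mixtures are far more variable than the two canned
mixtures used here.

## Numerical choices and validation scale

* Likelihood rescaling: partials normalised at every message with
  accumulated log scalers; marginals normalised per node.
* Optimisation: `nlminb`, relative tolerance $10^{-10}$, log-rate bounds
  $[10^{-8}, 10^3]$/Myr; a rate within 0.1% (log scale) of a bound sets the
  `boundary` flag, as does a monomorphic trait.
* Oracles in the test suite: brute-force enumeration over all $2^{m}$
  ancestral assignments for likelihoods and marginals (trees up to 6 tips,
  binary and polytomous, over a 5×5 rate grid, at $10^{-10}$/$10^{-9}$);
  `ape::matexpo` for the kernel; `phytools::fitMk` and
  `phytools::rerootingMethod` as independent implementations; a
  regular-expression oracle for the classifier; analytic Yule root-age
  moments for the tree generator.
* Parameter-recovery validation simulates 100 replicates of a 500-tip Yule
  tree (birth 0.1/Myr, matching the focal clade's $\ln(51)/41.3 \approx
  0.1$ diversification) under $q_{01} = 0.01$, $q_{10} = 0.15$, simulating
  from exactly the model being fitted (equal root prior); both rates land
  within a factor of 2 of truth in roughly 90% of replicates, with ARD
  preferred by AIC in nearly all. Robustness machinery is validated on a
  40-tip analogue with a 25-tip uniformly-FD clade at 200 simulations.
  These sizes keep the suite's Monte-Carlo error small relative to the
  asserted margins.

## Known limitations

* Two states only; no hidden-rate models, no stochastic character mapping,
  no uncertainty propagation over tree topologies or datings.
* Tip states enter as error-free; measurement error is explored only
  through the resampling schemes, not modelled in the likelihood.
* The rerooting method is approximate for ARD with a non-stationary prior
  (by construction); use the default up–down algorithm when exact marginals
  are wanted there.
* `label_notes()` is a two-cluster heuristic intended for well-separated
  note classes; it refuses ambiguous splits rather than resolving them.
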