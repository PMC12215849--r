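# fdcalls

Tits and chickadees (Paridae) combine two classes of calls — high-frequency,
narrowband **F notes** and broadband, noisy **D notes** — into a rigidly
ordered **FD** combination (the "chick-a-dee" call). `fdcalls` provides a
complete, testable pipeline for asking how old such a call combination is:

1. **Call classification.** Timed, labelled note streams are segmented into
   calls at long silences and classified into a six-way taxonomy (single
   note, repeated note, FD, DF, FxD, other combination). A call is FD only
   when it is one homogeneous block of F notes followed by one block of D
   notes: FDDDD and FFFFFFD are FD calls; FFFDDDFF and DDDDF are not.
2. **Species scoring.** A species is *FD-consistent* when at least one
   recording contains ≥ 5 calls of which strictly more than 50% are FD —
   evidence of consistent use in both form and context, not just occasional
   production. The FD:DF count ratio is reported as an order-preference
   diagnostic.
3. **Trait evolution.** The presence/absence of FD-consistency is a binary
   trait on a time-calibrated phylogeny, modelled as a two-state
   continuous-time Markov (Mk) process with gain rate `q01` and loss rate
   `q10` (per Myr). Likelihoods use Felsenstein's pruning algorithm; the
   equal-rates (ER) and all-rates-different (ARD) models are fitted by
   maximum likelihood and compared with AIC = −2 logL + 2k and
   BIC = −2 logL + k·log(n tips).
4. **Ancestral reconstruction.** Marginal posterior state probabilities at
   every internal node, by an exact up–down message pass or by the classical
   rerooting method, plus the probability of FD presence at any clade's most
   recent common ancestor.
5. **Robustness.** Resampling experiments that drop recordings at random,
   flip FD-positive species, or discount species whose pass rests on a
   single recording — refitting the model each time — to check that the
   ancestral conclusion is not an artefact of a few classifications.
6. **Synthetic data.** Seeded generators for Yule trees, exact CTMC trait
   histories, and note-level call corpora with realistic call-count and
   silence-gap structure, so the whole pipeline can be exercised and
   validated without any field recordings.

The package is tidyverse-native: tabular functions take a data frame first
and return tibbles, fitted objects have `tidy()`/`glance()` methods, and
result types have `autoplot()` methods. Trees are `ape::phylo` objects.

## Worked example

A synthetic study in the shape of the real question: a 41.3-Myr phylogeny of
40 species whose 25-species focal clade is uniformly FD-consistent, scored
from a simulated note-level corpus.

```r
library(fdcalls)
set.seed(1)

fd_clade <- simulate_tree(25, root_age_myr = 11.2, tip_prefix = "fd",  seed = 206)
outgroup <- simulate_tree(15, root_age_myr = 30,   tip_prefix = "out", seed = 207)
tree <- ape::read.tree(text = sprintf("(%s:30.1,%s:11.3);",
  sub(";$", "", ape::write.tree(fd_clade)),
  sub(";$", "", ape::write.tree(outgroup))))

trait <- tibble::tibble(species = tree$tip.label,
                        fd_present = as.integer(startsWith(tree$tip.label, "fd")))
corpus <- simulate_call_dataset(trait, seed = 3)
calls  <- classify_calls(segment_calls(corpus$notes))

res <- run_fd_analysis(tree, calls = calls, clade_tips = fd_clade$tip.label,
                       robustness = list(robustness_config("FLIP_SPECIES",
                                         p_flip = 0.1, n_sims = 200, seed = 42)))
res
#> FD call-combination analysis
#>   40 tips, 6970 calls, 25 FD-consistent species
#>   model selected by AIC: ER (dAIC to ARD = 1.94)
#>   ARD rates: gain q01 = 0.003728, loss q10 = 1e-08 (loss/gain = 0.00)
#>   P(FD at focal ancestor) = 1.0000
#>   robustness FLIP_SPECIES: 0.990 of 200 sims above 0.95
```

Reading the output: all 25 focal-clade species were recovered as
FD-consistent from their simulated recordings and every outgroup species was
not, so the reconstruction puts probability ≈ 1 on the FD combination being
present in the focal clade's common ancestor. With no observed losses the
ARD loss rate collapses to its lower bound and the one-parameter ER model
wins on AIC (ΔAIC = 1.94). The conclusion survives perturbation: in 99% of
200 simulations that randomly strip 10% of FD species of the trait, the
clade ancestor's probability stays above 0.95.

Individual stages are ordinary pipeable functions:

```r
segment_calls(notes) |> classify_calls() |> fd_consistency()
fit_mk(tree, trait, model = "ARD") |> generics::glance()
asr_marginal(tree, trait, q01 = 0.01, q10 = 0.15) |> ancestor_probability(clade)
```

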