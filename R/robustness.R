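#' Configuration for a robustness resampling experiment
#'
#' Three perturbation schemes probe how strongly the ancestral reconstruction
#' depends on the classification of individual recordings or species:
#'
#' * `DROP_RECORDINGS` — every recording is independently discarded with
#'   probability `p_drop` (as if it had been misclassified) and the
#'   FD-consistency criterion is recomputed from the survivors; a species
#'   left with no recordings scores 0.
#' * `FLIP_SPECIES` — every FD-positive species independently loses the
#'   trait with probability `p_flip`; negatives are never flipped.
#' * `SINGLE_RECORDING_STRINGENCY` — deterministic: species whose pass rests
#'   on exactly one qualifying recording are rescored 0.
#'
#' @param scheme One of the three scheme names above.
#' @param p_drop Per-recording drop probability (default 0.5).
#' @param p_flip Per-positive-species flip probability (default 0.10).
#' @param n_sims Number of simulations (default 1000).
#' @param prob_threshold The ancestral-probability threshold whose exceedance
#'   fraction is reported (default 0.95, strict `>`).
#' @param seed Integer seed making the experiment fully reproducible.
#' @return A list of class `robustness_config`.
#' @export
robustness_config <- function(scheme = c("DROP_RECORDINGS", "FLIP_SPECIES",
                                         "SINGLE_RECORDING_STRINGENCY"),
                              p_drop = 0.5, p_flip = 0.10, n_sims = 1000L,
                              prob_threshold = 0.95, seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(p_drop >= 0, p_drop <= 1, p_flip >= 0, p_flip <= 1,
            n_sims >= 1L, prob_threshold >= 0, prob_threshold <= 1)
  structure(list(scheme = scheme, p_drop = p_drop, p_flip = p_flip,
                 n_sims = as.integer(n_sims), prob_threshold = prob_threshold,
                 seed = as.integer(seed)),
            class = "robustness_config")
}

#' Per-recording FD qualification table
#'
#' One row per recording with its FD-qualification flag under the given
#' thresholds — the lean summary the resampling schemes operate on. Passing
#' this to [resample_recordings()] instead of the raw call table avoids
#' recomputing it on every draw.
#'
#' @inheritParams fd_consistency
#' @return A data frame `(species, recording_id, qualifies)`.
#' @export
recording_qualification <- function(calls, min_calls = 5L, min_prop = 0.5) {
  if (all(c("species", "recording_id", "qualifies") %in% names(calls))) {
    return(calls)   # already a qualification table
  }
  prof <- per_recording_profile(calls)
  data.frame(species = prof$species,
             recording_id = prof$recording_id,
             qualifies = prof$n_calls >= min_calls &
               prof$FD / prof$n_calls > min_prop)
}

trait_from_qualification <- function(qual, keep, species_levels) {
  passed <- tapply(qual$qualifies & keep,
                   factor(qual$species, levels = species_levels), any)
  tibble::tibble(species = species_levels,
                 fd_present = as.integer(!is.na(passed) & passed))
}

#' Perturb the trait by randomly dropping recordings
#'
#' Each recording is independently removed with probability `p_drop`, then
#' the FD-consistency criterion is recomputed per species on the surviving
#' recordings (rather than flipping the trait directly, so a species with
#' several qualifying recordings is much harder to dislodge than one relying
#' on a single recording). A species whose recordings are all dropped scores
#' 0.
#'
#' @inheritParams fd_consistency
#' @param calls A call-level table, or a precomputed
#'   [recording_qualification()] table for repeated draws.
#' @param p_drop Drop probability in \[0, 1\].
#' @param species_levels Optional full species vector fixing the output rows
#'   (defaults to the species present in `calls`).
#' @return A tibble `(species, fd_present)`.
#' @export
resample_recordings <- function(calls, p_drop = 0.5, min_calls = 5L,
                                min_prop = 0.5, species_levels = NULL) {
  qual <- recording_qualification(calls, min_calls, min_prop)
  if (is.null(species_levels)) species_levels <- sort(unique(qual$species))
  keep <- stats::runif(nrow(qual)) >= p_drop
  trait_from_qualification(qual, keep, species_levels)
}

#' Perturb the trait by flipping FD-positive species to negative
#'
#' @param trait A tibble `(species, fd_present)`.
#' @param p_flip Probability that each positive species is set to 0;
#'   negatives are never flipped (the perturbation models over-crediting a
#'   species with the combination, not under-crediting).
#' @return The perturbed trait tibble.
#' @export
flip_species <- function(trait, p_flip = 0.10) {
  stopifnot(is.data.frame(trait),
            all(c("species", "fd_present") %in% names(trait)),
            p_flip >= 0, p_flip <= 1)
  flips <- trait$fd_present == 1L & stats::runif(nrow(trait)) < p_flip
  dplyr::mutate(tibble::as_tibble(trait),
                fd_present = ifelse(flips, 0L, .data$fd_present))
}

#' Rescore species that pass on a single recording as negative
#'
#' Deterministic stringency variant: a species whose FD-consistency pass
#' rests on exactly one qualifying recording is counted as not passing;
#' species with two or more qualifying recordings (or none) are unchanged.
#'
#' @inheritParams resample_recordings
#' @return A tibble `(species, fd_present)`.
#' @export
single_recording_stringency <- function(calls, min_calls = 5L,
                                        min_prop = 0.5,
                                        species_levels = NULL) {
  qual <- recording_qualification(calls, min_calls, min_prop)
  if (is.null(species_levels)) species_levels <- sort(unique(qual$species))
  n_qual <- tapply(qual$qualifies,
                   factor(qual$species, levels = species_levels), sum)
  n_qual[is.na(n_qual)] <- 0L
  tibble::tibble(species = species_levels,
                 fd_present = as.integer(n_qual >= 2L))
}

#' Run a robustness resampling experiment
#'
#' For each of `config$n_sims` simulations: perturb the trait under the
#' configured scheme, refit the ARD Mk model from scratch on the perturbed
#' trait, rerun the marginal ancestral reconstruction, and record the
#' probability of state 1 at the focal clade's ancestor. Reports the
#' fraction of simulations in which that probability strictly exceeds
#' `config$prob_threshold`. Replicates whose perturbed trait is monomorphic
#' are retained with their boundary-rate fits and flagged, never silently
#' dropped; outright fit failures are recorded as missing. Refits use the
#' deterministic optimiser starts (the moment-style start plus the ER
#' optimum), so identical perturbed traits give bit-identical results and
#' the whole experiment is a pure function of the seed.
#'
#' @inheritParams fd_consistency
#' @param tree A rooted `phylo`; every tip must appear in `calls`.
#' @param config A [robustness_config()].
#' @param clade_tips Tips defining the focal ancestor (default: all tips,
#'   i.e. the root).
#' @param root_prior Root prior for fitting and reconstruction.
#' @return An object of class `robustness_result`: per-simulation tibble
#'   (`sim`, `p1`, `boundary`, `failed`), `fraction_above_threshold`,
#'   summary quantiles, the baseline (unperturbed) ancestor probability, and
#'   the config. [generics::tidy()] returns the per-simulation tibble,
#'   [generics::glance()] the one-row summary.
#' @export
robustness_experiment <- function(tree, calls, config, clade_tips = NULL,
                                  min_calls = 5L, min_prop = 0.5,
                                  root_prior = "equal") {
  stopifnot(inherits(config, "robustness_config"), inherits(tree, "phylo"))
  if (is.null(clade_tips)) clade_tips <- tree$tip.label
  baseline_cons <- fd_consistency(calls, min_calls, min_prop)
  baseline_trait <- build_trait_vector(baseline_cons, tree)
  qual <- recording_qualification(calls, min_calls, min_prop)
  tips <- tree$tip.label

  eval_trait <- function(trait) {
    fit <- tryCatch(
      fit_mk(tree, trait, model = "ARD", root_prior = root_prior,
             n_starts = 1L),
      error = function(e) NULL)
    if (is.null(fit)) return(c(NA_real_, NA))
    asr <- asr_marginal(fit = fit)
    c(ancestor_probability(asr, clade_tips), fit$boundary)
  }

  run <- function() {
    baseline <- eval_trait(baseline_trait)
    sims <- matrix(NA_real_, config$n_sims, 2L)
    for (i in seq_len(config$n_sims)) {
      trait_i <- switch(config$scheme,
        DROP_RECORDINGS = {
          keep <- stats::runif(nrow(qual)) >= config$p_drop
          trait_from_qualification(qual, keep, tips)
        },
        FLIP_SPECIES = flip_species(baseline_trait, config$p_flip),
        SINGLE_RECORDING_STRINGENCY =
          single_recording_stringency(calls, min_calls, min_prop,
                                      species_levels = tips))
      sims[i, ] <- eval_trait(trait_i)
    }
    list(baseline = baseline, sims = sims)
  }
  res <- withr::with_seed(config$seed, run())

  sims <- tibble::tibble(
    sim = seq_len(config$n_sims),
    p1 = res$sims[, 1L],
    boundary = as.logical(res$sims[, 2L]),
    failed = is.na(res$sims[, 1L])
  )
  if (any(sims$failed)) {
    rlang::warn(sprintf("%d replicate fit(s) failed and are reported as missing",
                        sum(sims$failed)))
  }
  ok <- sims$p1[!sims$failed]
  structure(list(
    sims = sims,
    fraction_above_threshold = mean(ok > config$prob_threshold),
    quantiles = stats::quantile(ok, c(0.025, 0.25, 0.5, 0.75, 0.975),
                                names = TRUE),
    baseline_p1 = res$baseline[1L],
    n_failed = sum(sims$failed),
    config = config,
    clade_tips = clade_tips
  ), class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Robustness experiment: %s (n_sims = %d, seed = %d)\n",
              cfg$scheme, cfg$n_sims, cfg$seed))
  cat(sprintf("  baseline ancestor P(FD) = %.4f\n", x$baseline_p1))
  cat(sprintf("  fraction of simulations with P(FD) > %.2f: %.3f\n",
              cfg$prob_threshold, x$fraction_above_threshold))
  q <- x$quantiles
  cat(sprintf("  P(FD) quantiles: 2.5%% %.3f | 50%% %.3f | 97.5%% %.3f\n",
              q[[1L]], q[[3L]], q[[5L]]))
  if (x$n_failed > 0L) cat(sprintf("  %d failed replicate(s)\n", x$n_failed))
  invisible(x)
}

#' @export
tidy.robustness_result <- function(x, ...) x$sims

#' @export
glance.robustness_result <- function(x, ...) {
  tibble::tibble(scheme = x$config$scheme,
                 n_sims = x$config$n_sims,
                 fraction_above_threshold = x$fraction_above_threshold,
                 baseline_p1 = x$baseline_p1,
                 median_p1 = x$quantiles[[3L]],
                 n_failed = x$n_failed)
}
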