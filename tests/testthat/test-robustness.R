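# a species dataset with known per-recording qualification structure
make_species_calls <- function() {
  dplyr::bind_rows(
    # ten recordings, every one individually qualifying
    calls_from_counts("deep", as.list(rep(list(c(FD = 6, SINGLE = 2)), 10))),
    # exactly one qualifying recording
    calls_from_counts("shallow", list(c(FD = 6, SINGLE = 2),
                                      c(SINGLE = 8))),
    # never qualifies
    calls_from_counts("plain", list(c(SINGLE = 10), c(REPEATED = 5)))
  )
}

test_that("recording drop-out recomputes consistency on survivors", {
  calls <- make_species_calls()
  base <- fd_consistency(calls)
  sp <- sort(unique(calls$species))

  set.seed(61)
  none <- resample_recordings(calls, p_drop = 0, species_levels = sp)
  expect_equal(none$fd_present,
               as.integer(base$passes_fd[match(sp, base$species)]))

  all_dropped <- resample_recordings(calls, p_drop = 1, species_levels = sp)
  expect_equal(all_dropped$fd_present, c(0L, 0L, 0L))
})

test_that("drop-out survival follows the exact binomial formula", {
  calls <- make_species_calls()
  qual <- recording_qualification(calls)
  set.seed(62)
  n <- 10000
  kept <- replicate(n, {
    resample_recordings(qual, p_drop = 0.5,
                        species_levels = c("deep", "plain",
                                           "shallow"))$fd_present[1]
  })
  p_exact <- 1 - 0.5^10   # any of ten qualifying recordings survives
  expect_lt(abs(mean(kept) - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / n) + 1e-12)
})

test_that("species flipping only demotes positives, at the binomial rate", {
  trait <- tibble::tibble(species = paste0("s", 1:40),
                          fd_present = rep(c(1L, 0L), c(28L, 12L)))
  set.seed(63)
  expect_identical(flip_species(trait, 0), tibble::as_tibble(trait))
  expect_equal(sum(flip_species(trait, 1)$fd_present), 0L)

  n <- 10000
  flipped <- replicate(n, 28L - sum(flip_species(trait, 0.1)$fd_present))
  se <- sqrt(28 * 0.1 * 0.9 / n)
  expect_lt(abs(mean(flipped) - 2.8), 3 * se)
  # negatives never gain the trait
  expect_equal(sum(flip_species(trait, 0.5)$fd_present[29:40]), 0L)
})

test_that("single-recording stringency demotes exactly the fragile passes", {
  calls <- make_species_calls()
  out <- single_recording_stringency(calls)
  expect_equal(out$fd_present[out$species == "deep"], 1L)
  expect_equal(out$fd_present[out$species == "shallow"], 0L)
  expect_equal(out$fd_present[out$species == "plain"], 0L)

  # a corpus engineered with exactly 6 single-recording passers
  many <- dplyr::bind_rows(lapply(1:6, function(i) {
    calls_from_counts(paste0("frag", i), list(c(FD = 6), c(SINGLE = 6)))
  }), lapply(1:3, function(i) {
    calls_from_counts(paste0("solid", i), list(c(FD = 6), c(FD = 6)))
  }))
  base <- fd_consistency(many)
  strict <- single_recording_stringency(many)
  expect_equal(sum(base$passes_fd) - sum(strict$fd_present), 6L)
})

test_that("a null perturbation reproduces the baseline bit for bit", {
  study <- simulate_study(n_tips = 12, seed = 64, root_state = 1,
                          q01 = 0.02, q10 = 0.08,
                          call_config = list(recordings_per_species = 4L))
  calls <- classify_calls(segment_calls(study$notes))
  cfg <- robustness_config("DROP_RECORDINGS", p_drop = 0, n_sims = 5,
                           seed = 7)
  res <- robustness_experiment(study$tree, calls, cfg)
  expect_true(all(res$sims$p1 == res$baseline_p1))
  expect_true(res$fraction_above_threshold %in% c(0, 1))

  cfg2 <- robustness_config("FLIP_SPECIES", p_flip = 0, n_sims = 5, seed = 7)
  res2 <- robustness_experiment(study$tree, calls, cfg2)
  expect_true(all(res2$sims$p1 == res2$baseline_p1))
})

test_that("experiments are pure functions of their seed", {
  study <- simulate_study(n_tips = 10, seed = 65, root_state = 1,
                          q01 = 0.02, q10 = 0.08,
                          call_config = list(recordings_per_species = 3L))
  calls <- classify_calls(segment_calls(study$notes))
  cfg <- robustness_config("DROP_RECORDINGS", p_drop = 0.5, n_sims = 3,
                           seed = 11)
  r1 <- robustness_experiment(study$tree, calls, cfg)
  r2 <- robustness_experiment(study$tree, calls, cfg)
  expect_identical(r1$sims, r2$sims)
  expect_identical(r1$fraction_above_threshold, r2$fraction_above_threshold)
})

test_that("stronger flipping cannot make the ancestor more secure", {
  tr <- simulate_tree(20, root_age_myr = 40, seed = 66)
  # a confidently reconstructed scenario: most tips FD
  trait <- tibble::tibble(species = tr$tip.label,
                          fd_present = rep(c(1L, 0L), c(16L, 4L)))
  calls <- dplyr::bind_rows(lapply(seq_len(nrow(trait)), function(i) {
    mix <- if (trait$fd_present[i] == 1) c(FD = 6, SINGLE = 2) else
      c(SINGLE = 8)
    calls_from_counts(trait$species[i], list(mix, mix))
  }))
  frac <- vapply(c(0.05, 0.6), function(p) {
    cfg <- robustness_config("FLIP_SPECIES", p_flip = p, n_sims = 25,
                             seed = 13)
    robustness_experiment(tr, calls, cfg)$fraction_above_threshold
  }, numeric(1))
  expect_gte(frac[1], frac[2])
})
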