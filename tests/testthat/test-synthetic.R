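test_that("simulated trees are ultrametric, seeded and rescalable", {
  cherry <- simulate_tree(2, seed = 41)
  d <- ape::node.depth.edgelength(cherry)
  expect_equal(d[1], d[2])

  tr <- simulate_tree(51, root_age_myr = 41.3, seed = 42)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(tr)), 41.3)
  expect_equal(length(tr$tip.label), 51L)

  expect_identical(ape::write.tree(simulate_tree(10, seed = 43)),
                   ape::write.tree(simulate_tree(10, seed = 43)))
  expect_error(simulate_tree(10, birth = 0.1, death = 0.2), "death rate")
})

test_that("Yule root ages match the analytic expectation", {
  # E[root age | n tips] = sum_{k=2}^{n} 1 / (lambda k) under pure birth
  set.seed(44)
  lambda <- 0.5; n <- 10; reps <- 300
  ages <- replicate(reps, {
    max(ape::node.depth.edgelength(simulate_tree(n, birth = lambda)))
  })
  expected <- sum(1 / (lambda * (2:n)))
  expect_lt(abs(mean(ages) - expected), 3 * sd(ages) / sqrt(reps))
})

test_that("trait simulation respects degenerate and stationary regimes", {
  tr <- simulate_tree(20, seed = 45)
  frozen <- simulate_trait(tr, 1e-9, 1e-9, root_state = 0, seed = 46)
  expect_true(all(frozen$tip_states$fd_present == 0))
  expect_equal(nrow(frozen$events), 0L)

  # symmetric rates on long branches: tip frequencies near one half
  long <- simulate_tree(400, birth = 0.05, seed = 47)
  h <- simulate_trait(long, 0.5, 0.5, root_state = 0, seed = 48)
  expect_gt(mean(h$tip_states$fd_present), 0.35)
  expect_lt(mean(h$tip_states$fd_present), 0.65)
})

test_that("trait histories are consistent with their event lists", {
  tr <- simulate_tree(15, seed = 49)
  h <- simulate_trait(tr, 0.3, 0.3, seed = 50)
  tre <- ape::reorder.phylo(tr, "postorder")
  state_of <- c(setNames(h$tip_states$fd_present, seq_len(15)),
                setNames(h$node_states$state, h$node_states$node))
  for (i in seq_len(nrow(tre$edge))) {
    n_flips <- sum(h$events$edge == i)
    parent_st <- state_of[[as.character(tre$edge[i, 1])]]
    child_st <- state_of[[as.character(tre$edge[i, 2])]]
    expect_equal((parent_st + n_flips) %% 2, child_st %% 2)
  }
})

test_that("simulated tip-pair transitions match the transition kernel", {
  # one long star: tips are iid draws from P(t) given the root state
  n <- 10000
  star <- ape::read.tree(text = paste0(
    "(", paste0("t", 1:n, ":2.0", collapse = ","), "):0;"))
  h <- simulate_trait(star, 0.3, 0.7, root_state = 0, seed = 51)
  p01 <- mk_transition_matrix(0.3, 0.7, 2.0)[1, 2]
  emp <- mean(h$tip_states$fd_present)
  expect_lt(abs(emp - p01), 3 * sqrt(p01 * (1 - p01) / n))
})

test_that("call corpora mirror the configured structure", {
  trait <- tibble::tibble(species = c("fd_sp", "plain_sp"),
                          fd_present = c(1L, 0L))
  d <- simulate_call_dataset(trait, seed = 52)
  expect_equal(dplyr::n_distinct(d$calls$recording_id), 20L)

  per_rec <- dplyr::count(d$calls, recording_id)
  expect_true(all(per_rec$n >= 2 & per_rec$n <= 148))

  plain <- d$calls[d$calls$species == "plain_sp", ]
  expect_equal(sum(plain$category %in% c("FD", "DF", "FXD")), 0L)

  # determinism contract
  d2 <- simulate_call_dataset(trait, seed = 52)
  expect_identical(d$notes, d2$notes)

  bad <- list(mixture_non_fd = c(SINGLE = 0.4, REPEATED = 0.4, FD = 0.2,
                                 DF = 0, FXD = 0, OTHER_COMBINATION = 0))
  expect_error(simulate_call_dataset(trait, config = bad), "zero FD")
})

test_that("segment + classify recovers the generating calls and categories", {
  trait <- tibble::tibble(species = c("a", "b", "c"),
                          fd_present = c(1L, 1L, 0L))
  d <- simulate_call_dataset(trait, seed = 53,
                             config = list(recordings_per_species = 4L))
  calls <- classify_calls(segment_calls(d$notes, gap_threshold = 0.6))
  joined <- dplyr::inner_join(
    calls, d$calls, by = c("species", "recording_id", "call_id"),
    suffix = c("_est", "_true"))
  expect_equal(nrow(joined), nrow(d$calls))
  expect_gte(mean(joined$category_est == joined$category_true), 0.999)
})

test_that("FD species pass consistency with near certainty at the defaults", {
  set.seed(54)
  trials <- 60
  passes <- replicate(trials, {
    d <- simulate_call_dataset(
      tibble::tibble(species = "x", fd_present = 1L),
      config = list(recordings_per_species = 10L))
    fd_consistency(d$calls)$passes_fd
  })
  expect_gte(mean(passes), 0.99)
})

test_that("confident reconstructions are calibrated against true histories", {
  # among internal nodes reconstructed with p1 in [0.9, 1], the true state
  # should be 1 in the vast majority of histories
  set.seed(56)
  tr <- simulate_tree(30, birth = 0.1)
  hits <- 0L; conf <- 0L
  for (i in 1:200) {
    h <- simulate_trait(tr, 0.05, 0.05)
    if (length(unique(h$tip_states$fd_present)) < 2) next
    asr <- asr_marginal(tr, h$tip_states, 0.05, 0.05)
    sure <- which(asr$p1 >= 0.9)
    conf <- conf + length(sure)
    truth <- h$node_states$state[match(asr$node[sure], h$node_states$node)]
    hits <- hits + sum(truth == 1L)
  }
  expect_gt(conf, 50)   # the regime actually produces confident nodes
  expect_gte(hits / conf, 0.85)
})

test_that("the full pipeline recovers simulated tip traits exactly", {
  study <- simulate_study(n_tips = 15, seed = 55, root_state = 1,
                          q01 = 0.02, q10 = 0.05,
                          call_config = list(recordings_per_species = 5L))
  calls <- classify_calls(segment_calls(study$notes))
  tv <- build_trait_vector(fd_consistency(calls), study$tree)
  expect_equal(tv$fd_present, study$trait$fd_present)
})
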