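#' Simulate an ultrametric birth-death (default Yule) tree
#'
#' Thin, seeded wrapper around [ape::rphylo()] conditioned on the number of
#' tips, optionally rescaled so the root age matches a target depth in Myr
#' (e.g. 41.3 Myr to mimic a Paridae-plus-outgroups chronogram).
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate per Myr (> 0).
#' @param death Extinction rate per Myr (>= 0, default 0 = pure-birth Yule).
#' @param root_age_myr Optional target root age; the whole tree is rescaled
#'   so the root sits exactly at this depth.
#' @param tip_prefix Tip labels are `paste0(tip_prefix, 1:n_tips)`.
#' @param seed Optional integer; when given the simulation is a pure
#'   function of its arguments.
#' @return A rooted ultrametric `phylo` object.
#' @export
simulate_tree <- function(n_tips, birth = 0.1, death = 0,
                          root_age_myr = NULL, tip_prefix = "sp",
                          seed = NULL) {
  stopifnot(n_tips >= 2, birth > 0, death >= 0)
  if (death >= birth) {
    rlang::abort("death rate must be below the birth rate for a surviving clade")
  }
  sim <- function() {
    tr <- ape::rphylo(n_tips, birth = birth, death = death)
    tr$tip.label <- paste0(tip_prefix, seq_len(n_tips))
    if (!is.null(root_age_myr)) {
      depth <- max(ape::node.depth.edgelength(tr))
      tr$edge.length <- tr$edge.length * (root_age_myr / depth)
    }
    tr
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate a binary trait history along a phylogeny
#'
#' Exact forward simulation of the two-state continuous-time Markov chain:
#' along each branch, waiting times to the next flip are exponential with
#' rate `q01` (in state 0) or `q10` (in state 1). True states at internal
#' nodes and every transition event are returned, so reconstructions can be
#' scored against the generating history.
#'
#' @inheritParams mk_loglik
#' @param root_state `0`, `1`, or `NULL` to draw the root from `root_prior`.
#' @param root_prior Prior used when `root_state` is `NULL`.
#' @param seed Optional integer seed.
#' @return A list of class `trait_history`: `tip_states` (tibble `species`,
#'   `fd_present`), `node_states` (tibble `node`, `state` including the
#'   root), and `events` (tibble `edge`, `time_myr` along the branch,
#'   `from`, `to`).
#' @export
simulate_trait <- function(tree, q01, q10, root_state = NULL,
                           root_prior = "equal", seed = NULL) {
  check_rates(q01, q10)
  stopifnot(inherits(tree, "phylo"))
  sim <- function() {
    tre <- ape::reorder.phylo(tree, "postorder")
    n_tip <- length(tre$tip.label)
    n_all <- n_tip + tre$Nnode
    root <- n_tip + 1L
    state <- integer(n_all)
    state[root] <- if (!is.null(root_state)) {
      stopifnot(root_state %in% c(0L, 1L))
      as.integer(root_state)
    } else {
      pi <- root_prior_probs(root_prior, q01, q10)
      stats::rbinom(1L, 1L, pi[2L])
    }
    events <- list()
    rates <- c(q01, q10)   # flip rate out of state 0, state 1
    for (i in rev(seq_len(nrow(tre$edge)))) {   # preorder
      p <- tre$edge[i, 1L]; ch <- tre$edge[i, 2L]
      len <- tre$edge.length[i]
      st <- state[p]
      at <- 0
      repeat {
        wait <- stats::rexp(1L, rates[st + 1L])
        if (at + wait > len) break
        at <- at + wait
        events[[length(events) + 1L]] <-
          c(edge = i, time_myr = at, from = st, to = 1L - st)
        st <- 1L - st
      }
      state[ch] <- st
    }
    ev <- if (length(events) > 0L) {
      tibble::as_tibble(do.call(rbind, events))
    } else {
      tibble::tibble(edge = integer(), time_myr = numeric(),
                     from = integer(), to = integer())
    }
    structure(list(
      tip_states = tibble::tibble(species = tre$tip.label,
                                  fd_present = state[seq_len(n_tip)]),
      node_states = tibble::tibble(node = root:n_all,
                                   state = state[root:n_all]),
      events = ev,
      tree = tree, q01 = q01, q10 = q10
    ), class = "trait_history")
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Default call-corpus generator settings
#'
#' Study-scale defaults for [simulate_call_dataset()]: 10 recordings per
#' species; calls per recording negative-binomial with mean 16.5 and SD 14.9
#' truncated to \[2, 148\]; within-call silences lognormal with median 0.09 s
#' and between-call silences with median 2.55 s (log-sd 0.4 each, so the two
#' distributions stay disjoint in practice); F blocks geometric with mean 2
#' notes and D blocks with mean 4; per-species category mixtures in which
#' FD-producing species put 60% of their calls in the FD category and
#' species without the combination produce no FD, DF or FxD calls at all.
#'
#' @return A named list of settings, any of which can be overridden through
#'   the `config` argument of [simulate_call_dataset()].
#' @export
call_sim_defaults <- function() {
  list(
    recordings_per_species = 10L,
    calls_mean = 16.5,
    calls_sd = 14.93,
    calls_range = c(2L, 148L),
    intra_gap_median_s = 0.09,
    inter_gap_median_s = 2.55,
    gap_log_sd = 0.4,
    note_duration_s = 0.1,
    f_block_mean = 2,
    d_block_mean = 4,
    mixture_fd = c(SINGLE = 0.15, REPEATED = 0.15, FD = 0.60, DF = 0.02,
                   FXD = 0.02, OTHER_COMBINATION = 0.06),
    mixture_non_fd = c(SINGLE = 0.45, REPEATED = 0.35, FD = 0, DF = 0,
                       FXD = 0, OTHER_COMBINATION = 0.20)
  )
}

# block length >= 1, geometric with the given mean
rblock <- function(n, mean_len) 1L + stats::rgeom(n, prob = 1 / mean_len)

realize_call_labels <- function(category, cfg) {
  f <- function() rblock(1L, cfg$f_block_mean)
  d <- function() rblock(1L, cfg$d_block_mean)
  switch(category,
    SINGLE = sample(c("F", "D", "OTHER"), 1L),
    REPEATED = rep(sample(c("F", "D", "OTHER"), 1L), 1L + rblock(1L, 2)),
    FD = c(rep("F", f()), rep("D", d())),
    DF = c(rep("D", d()), rep("F", f())),
    FXD = {
      n_blocks <- 3L + stats::rpois(1L, 1L)
      first <- sample(c("F", "D"), 1L)
      unlist(lapply(seq_len(n_blocks), function(i) {
        lab <- if ((i %% 2L) == 1L) first else setdiff(c("F", "D"), first)
        rep(lab, if (lab == "F") f() else d())
      }))
    },
    OTHER_COMBINATION = {
      base <- c(rep(sample(c("F", "D"), 1L), f()), rep("OTHER", d()))
      if (stats::runif(1L) < 0.5) base else rev(base)
    },
    rlang::abort(paste0("unknown category: ", category))
  )
}

#' Simulate a note-level call corpus for a set of species
#'
#' Generates, for every species in a binary trait table, a set of recordings
#' laid out as timed note events in the format [segment_calls()] consumes.
#' Species with the trait draw their call categories from an FD-rich mixture
#' (and therefore pass the FD-consistency criterion with near certainty at
#' the defaults); species without it never produce FD, DF or FxD calls.
#' Within-call and between-call silences come from two disjoint lognormal
#' distributions, so segmenting at any threshold between them recovers the
#' generating calls exactly.
#'
#' @param trait A tibble `(species, fd_present)` — e.g. tip states from
#'   [simulate_trait()] — marking which species produce FD calls.
#' @param config Named list of overrides of [call_sim_defaults()].
#' @param seed Optional integer seed.
#' @return A list with `notes` (the note-level tibble: `species`,
#'   `recording_id`, `note_index`, `label`, `onset_s`, `offset_s`), `calls`
#'   (the generating call-level tibble with true `category`), and `config`.
#' @export
simulate_call_dataset <- function(trait, config = list(), seed = NULL) {
  stopifnot(is.data.frame(trait),
            all(c("species", "fd_present") %in% names(trait)))
  cfg <- utils::modifyList(call_sim_defaults(), config)
  for (mx in c("mixture_fd", "mixture_non_fd")) {
    m <- cfg[[mx]]
    if (!setequal(names(m), call_categories) || abs(sum(m) - 1) > 1e-8 ||
        any(m < 0)) {
      rlang::abort(paste0(mx, " must be a probability vector over the six call categories"))
    }
  }
  if (any(cfg$mixture_non_fd[c("FD", "DF", "FXD")] > 0)) {
    rlang::abort("species without the trait must have zero FD/DF/FXD mass")
  }
  if (cfg$intra_gap_median_s >= cfg$inter_gap_median_s) {
    rlang::abort("intra-call gap median must be below the inter-call median")
  }
  sim <- function() {
    nb_size <- cfg$calls_mean^2 / (cfg$calls_sd^2 - cfg$calls_mean)
    draw_n_calls <- function() {
      repeat {
        n <- stats::rnbinom(1L, size = nb_size, mu = cfg$calls_mean)
        if (n >= cfg$calls_range[1L] && n <= cfg$calls_range[2L]) return(n)
      }
    }
    rows <- list()
    call_rows <- list()
    for (sp_i in seq_len(nrow(trait))) {
      sp <- trait$species[sp_i]
      mix <- if (trait$fd_present[sp_i] == 1) cfg$mixture_fd else
        cfg$mixture_non_fd
      for (rec in seq_len(cfg$recordings_per_species)) {
        rec_id <- sprintf("%s_rec%02d", sp, rec)
        n_calls <- draw_n_calls()
        cats <- sample(names(mix), n_calls, replace = TRUE, prob = mix)
        t_cursor <- 0
        note_i <- 0L
        for (ci in seq_len(n_calls)) {
          labs <- realize_call_labels(cats[ci], cfg)
          if (ci > 1L) {
            t_cursor <- t_cursor +
              stats::rlnorm(1L, log(cfg$inter_gap_median_s), cfg$gap_log_sd)
          }
          nn <- length(labs)
          gaps <- if (nn > 1L) {
            stats::rlnorm(nn - 1L, log(cfg$intra_gap_median_s),
                          cfg$gap_log_sd)
          } else numeric(0)
          onsets <- t_cursor +
            cumsum(c(0, gaps + cfg$note_duration_s))
          offsets <- onsets + cfg$note_duration_s
          t_cursor <- offsets[nn]
          rows[[length(rows) + 1L]] <- tibble::tibble(
            species = sp, recording_id = rec_id,
            note_index = note_i + seq_len(nn),
            label = labs, onset_s = onsets, offset_s = offsets)
          note_i <- note_i + nn
          call_rows[[length(call_rows) + 1L]] <- tibble::tibble(
            species = sp, recording_id = rec_id, call_id = ci,
            category = cats[ci], n_notes = nn)
        }
      }
    }
    list(notes = dplyr::bind_rows(rows),
         calls = dplyr::bind_rows(call_rows) |>
           dplyr::mutate(category = factor(.data$category,
                                           levels = call_categories)),
         config = cfg)
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate a complete synthetic study: tree, trait history, call corpus
#'
#' Convenience wrapper chaining [simulate_tree()], [simulate_trait()] and
#' [simulate_call_dataset()] into one seeded object, handy as a ground-truth
#' fixture for the full pipeline.
#'
#' @inheritParams simulate_tree
#' @inheritParams mk_loglik
#' @param root_state Root state passed to [simulate_trait()].
#' @param call_config Overrides of [call_sim_defaults()].
#' @param seed Integer seed controlling all three stages.
#' @return A list with `tree`, `history`, `notes`, `calls`, `trait`.
#' @export
simulate_study <- function(n_tips = 40L, birth = 0.1, root_age_myr = 41.3,
                           q01 = 0.01, q10 = 0.15, root_state = NULL,
                           call_config = list(), seed = 1L) {
  tree <- simulate_tree(n_tips, birth = birth, root_age_myr = root_age_myr,
                        seed = seed)
  history <- simulate_trait(tree, q01 = q01, q10 = q10,
                            root_state = root_state, seed = seed + 1L)
  corpus <- simulate_call_dataset(history$tip_states,
                                  config = call_config, seed = seed + 2L)
  list(tree = tree, history = history, notes = corpus$notes,
       calls = corpus$calls, trait = history$tip_states,
       config = corpus$config)
}
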