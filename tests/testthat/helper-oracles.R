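# Independent oracles used across the suite. These deliberately avoid the
# package's own pruning/rerooting code paths.

# Brute-force likelihood: sum over all 2^Nnode assignments of internal-node
# states of prior(root) * prod over edges of P[parent_state, child_state](t).
enum_loglik <- function(tree, states, q01, q10, root_prior = "equal") {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  pi <- if (root_prior == "equal") c(0.5, 0.5) else
    c(q10, q01) / (q01 + q10)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(i) mk_transition_matrix(q01, q10, tree$edge.length[i]))
  states <- states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(0:1), n_node)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    full <- c(states, grid[g, ])
    lik <- pi[full[root] + 1L]
    for (i in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[i]][full[tree$edge[i, 1L]] + 1L,
                          full[tree$edge[i, 2L]] + 1L]
    }
    total <- total + lik
  }
  log(total)
}

# Brute-force marginals: accumulate the same enumeration per internal node
# and state, then normalise.
enum_marginals <- function(tree, states, q01, q10, root_prior = "equal") {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  root <- n_tip + 1L
  pi <- if (root_prior == "equal") c(0.5, 0.5) else
    c(q10, q01) / (q01 + q10)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(i) mk_transition_matrix(q01, q10, tree$edge.length[i]))
  states <- states[tree$tip.label]
  grid <- as.matrix(expand.grid(rep(list(0:1), n_node)))
  acc <- matrix(0, n_node, 2L)
  for (g in seq_len(nrow(grid))) {
    full <- c(states, grid[g, ])
    lik <- pi[full[root] + 1L]
    for (i in seq_len(nrow(tree$edge))) {
      lik <- lik * P[[i]][full[tree$edge[i, 1L]] + 1L,
                          full[tree$edge[i, 2L]] + 1L]
    }
    for (v in seq_len(n_node)) {
      acc[v, grid[g, v] + 1L] <- acc[v, grid[g, v] + 1L] + lik
    }
  }
  acc / rowSums(acc)
}

# Regular-expression oracle for the six-way call taxonomy.
regex_classify <- function(labels) {
  s <- paste(ifelse(labels == "OTHER", "o", labels), collapse = "")
  if (nchar(s) == 1L) return("SINGLE")
  if (grepl("^(.)\\1+$", s)) return("REPEATED")
  if (grepl("^F+D+$", s)) return("FD")
  if (grepl("^D+F+$", s)) return("DF")
  if (grepl("^[FD]+$", s)) return("FXD")
  "OTHER_COMBINATION"
}

# Random rooted tree, optionally with polytomies and zero-length branches.
random_test_tree <- function(n_tips, polytomy = FALSE) {
  tr <- ape::rtree(n_tips)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  if (polytomy && tr$Nnode > 1L) {
    internal <- which(tr$edge[, 2L] > n_tips)
    kill <- internal[seq_len(min(1L, length(internal)))]
    tr$edge.length[kill] <- 0
    tr <- ape::di2multi(tr, tol = 1e-12)
  }
  tr
}

random_states <- function(tree) {
  stats::setNames(sample(0:1, length(tree$tip.label), replace = TRUE),
                  tree$tip.label)
}

# A note-level recording laid out from explicit inter-note gaps.
notes_from_gaps <- function(labels, gaps, species = "sp1", rec = "r1",
                            dur = 0.1) {
  onsets <- cumsum(c(0, gaps + dur))
  tibble::tibble(species = species, recording_id = rec,
                 note_index = seq_along(labels), label = labels,
                 onset_s = onsets, offset_s = onsets + dur)
}

# Call-level table from per-recording category count lists.
calls_from_counts <- function(species, recs) {
  rows <- list()
  for (r in seq_along(recs)) {
    cats <- rep(names(recs[[r]]), unlist(recs[[r]]))
    if (length(cats) == 0L) next
    rows[[r]] <- tibble::tibble(species = species,
                                recording_id = paste0("r", r),
                                call_id = seq_along(cats), category = cats)
  }
  dplyr::bind_rows(rows)
}
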