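#' Marginal ancestral-state reconstruction for a binary trait
#'
#' For each internal node, the marginal posterior probability of states 0 and
#' 1 given the tip data and the supplied transition rates. Two algorithms are
#' available:
#'
#' * `"updown"` (default): one postorder (pruning) pass followed by a
#'   preorder pass propagating the above-node information; this computes the
#'   exact marginal under the prior placed at the tree's root, for any rates.
#' * `"reroot"`: the rerooting method — each internal node is treated in turn
#'   as the root and the root prior is combined with its conditional
#'   likelihoods there. Rerooting coincides with the exact marginal whenever
#'   the chain is reversible with respect to the root prior (always for ER
#'   with the equal prior; for ARD when `root_prior = "stationary"`). Under
#'   ARD with the equal prior it is the classical approximation.
#'
#' @inheritParams mk_loglik
#' @param fit Optionally, an `mk_fit` from [fit_mk()]; its tree, trait,
#'   rates and root prior are used and the other arguments may be omitted.
#' @param method `"updown"` or `"reroot"`.
#' @return An object of class `mk_asr`: a tibble with one row per internal
#'   node (`node` — ape node id, `p0`, `p1`, and `age_myr` when the tree is
#'   ultrametric), carrying the tree and rates as attributes. `p0 + p1 = 1`
#'   at every node. [generics::tidy()] returns the tibble.
#' @export
asr_marginal <- function(tree = NULL, trait = NULL, q01 = NULL, q10 = NULL,
                         root_prior = "equal", fit = NULL,
                         method = c("updown", "reroot")) {
  method <- match.arg(method)
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "mk_fit"))
    tree <- fit$tree
    trait <- fit$states
    q01 <- fit$rates[["q01"]]
    q10 <- fit$rates[["q10"]]
    root_prior <- fit$root_prior
  }
  check_rates(q01, q10)
  root_prior <- match.arg(root_prior, c("equal", "stationary"))
  pd <- tree_pruning_data(tree)
  states <- as_trait_vector(trait, list(tip.label = pd$tip_label))
  marg <- switch(method,
                 updown = asr_updown(pd, states, q01, q10, root_prior),
                 reroot = asr_reroot(tree, pd, states, q01, q10, root_prior))
  nodes <- pd$n_tip + seq_len(pd$n_node)
  out <- tibble::tibble(node = nodes,
                        p0 = marg[nodes, 1L],
                        p1 = marg[nodes, 2L])
  if (ape::is.ultrametric(tree, tol = 1e-6)) {
    depth <- ape::node.depth.edgelength(tree)
    out$age_myr <- max(depth) - depth[nodes]
  }
  structure(out,
            class = c("mk_asr", class(out)),
            tree = tree,
            rates = c(q01 = q01, q10 = q10),
            root_prior = root_prior,
            method = method)
}

# Exact marginals by the up-down (outside-inside) algorithm: down partials
# from prune_down(), then a preorder sweep accumulating each node's
# above-tree likelihood. All vectors are normalised node-wise; the
# normalisations cancel in the per-node posterior.
asr_updown <- function(pd, states, q01, q10, root_prior) {
  down <- prune_down(pd, states, q01, q10, root_prior)
  if (!is.finite(down$loglik)) {
    rlang::abort("data have zero likelihood under these rates")
  }
  n_all <- pd$n_tip + pd$n_node
  s <- q01 + q10
  # normalised down partials per node
  dn <- cbind(down$L0, down$L1)
  dn <- dn / pmax(dn[, 1L], dn[, 2L])
  # per-edge message S_e(s') = sum_{s''} P_{s',s''}(t_e) * dn_child(s'')
  ne <- length(pd$parent)
  M0 <- numeric(ne); M1 <- numeric(ne)
  for (i in seq_len(ne)) {
    e <- exp(-s * pd$elen[i]); ch <- pd$child[i]
    M0[i] <- ((q10 + q01 * e) * dn[ch, 1L] + q01 * (1 - e) * dn[ch, 2L]) / s
    M1[i] <- (q10 * (1 - e) * dn[ch, 1L] + (q01 + q10 * e) * dn[ch, 2L]) / s
  }
  U <- matrix(0, n_all, 2L)
  U[pd$root, ] <- root_prior_probs(root_prior, q01, q10)
  # edges of each parent (postorder edge list groups a node's child edges,
  # but index them explicitly to stay polytomy-safe)
  edges_of <- split(seq_len(ne), pd$parent)
  for (i in rev(seq_len(ne))) {   # preorder: parents before children
    p <- pd$parent[i]; ch <- pd$child[i]
    sibs <- setdiff(edges_of[[as.character(p)]], i)
    t0 <- U[p, 1L]; t1 <- U[p, 2L]
    for (j in sibs) { t0 <- t0 * M0[j]; t1 <- t1 * M1[j] }
    e <- exp(-s * pd$elen[i])
    u0 <- t0 * (q10 + q01 * e) / s + t1 * q10 * (1 - e) / s
    u1 <- t0 * q01 * (1 - e) / s + t1 * (q01 + q10 * e) / s
    m <- max(u0, u1)
    U[ch, ] <- c(u0, u1) / m
  }
  post <- dn * U
  post / rowSums(post)
}

# Literal rerooting: for each internal node, run a pruning pass over the
# undirected tree oriented away from that node, and combine the root prior
# with the conditional likelihoods obtained there.
asr_reroot <- function(tree, pd, states, q01, q10, root_prior) {
  n_all <- pd$n_tip + pd$n_node
  nbr <- vector("list", n_all)
  for (i in seq_along(pd$parent)) {
    p <- pd$parent[i]; ch <- pd$child[i]; t <- pd$elen[i]
    nbr[[p]] <- rbind(nbr[[p]], c(ch, t))
    nbr[[ch]] <- rbind(nbr[[ch]], c(p, t))
  }
  pi <- root_prior_probs(root_prior, q01, q10)
  s <- q01 + q10
  post <- matrix(NA_real_, n_all, 2L)
  for (v in (pd$n_tip + 1L):n_all) {
    # iterative postorder over the tree rooted at v
    stack <- list(c(v, NA_real_, NA_real_))  # node, parent, edge length
    order <- list()
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      order[[length(order) + 1L]] <- top
      nb <- nbr[[top[1L]]]
      if (!is.null(nb)) {
        for (r in seq_len(nrow(nb))) {
          if (is.na(top[2L]) || nb[r, 1L] != top[2L]) {
            stack[[length(stack) + 1L]] <- c(nb[r, 1L], top[1L], nb[r, 2L])
          }
        }
      }
    }
    P0 <- numeric(n_all); P1 <- numeric(n_all)
    tips <- seq_len(pd$n_tip)
    P0[tips] <- 1 - states; P1[tips] <- states
    P0[-tips] <- 1; P1[-tips] <- 1
    for (k in rev(seq_along(order))) {
      nd <- order[[k]]
      if (is.na(nd[2L])) next
      child <- nd[1L]; par <- nd[2L]
      e <- exp(-s * nd[3L])
      m <- max(P0[child], P1[child])
      c0 <- P0[child] / m; c1 <- P1[child] / m
      P0[par] <- P0[par] * ((q10 + q01 * e) * c0 + q01 * (1 - e) * c1) / s
      P1[par] <- P1[par] * (q10 * (1 - e) * c0 + (q01 + q10 * e) * c1) / s
    }
    w <- c(pi[1L] * P0[v], pi[2L] * P1[v])
    post[v, ] <- w / sum(w)
  }
  post
}

#' @export
tidy.mk_asr <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
print.mk_asr <- function(x, ...) {
  r <- attr(x, "rates")
  cat(sprintf("Marginal ancestral reconstruction (%s, root prior: %s)\n",
              attr(x, "method"), attr(x, "root_prior")))
  cat(sprintf("  rates: q01 = %.6g, q10 = %.6g; %d internal nodes\n",
              r[["q01"]], r[["q10"]], nrow(x)))
  print(tibble::as_tibble(unclass(x)), ...)
  invisible(x)
}

#' Posterior probability of the trait at a clade's common ancestor
#'
#' Looks up the reconstructed probability of state 1 (FD present) at the most
#' recent common ancestor of a set of tips — e.g. the probability that the
#' common ancestor of all Paridae in the tree already used the FD
#' combination.
#'
#' @param asr An `mk_asr` object from [asr_marginal()].
#' @param clade_tips Character vector of two or more tip labels. Tips are
#'   observed data, not reconstructions, so a single tip is an error.
#' @return The probability of state 1 at the clade's MRCA.
#' @export
ancestor_probability <- function(asr, clade_tips) {
  stopifnot(inherits(asr, "mk_asr"))
  tree <- attr(asr, "tree")
  clade_tips <- unique(as.character(clade_tips))
  unknown <- setdiff(clade_tips, tree$tip.label)
  if (length(unknown) > 0L) {
    rlang::abort(paste0("unknown tip(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(clade_tips) < 2L) {
    rlang::abort("clade_tips must contain at least two tips; a single tip is observed data, not a reconstruction")
  }
  node <- if (length(clade_tips) == length(tree$tip.label)) {
    length(tree$tip.label) + 1L
  } else {
    ape::getMRCA(tree, clade_tips)
  }
  asr$p1[match(node, asr$node)]
}
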