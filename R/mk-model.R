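#' Two-state Mk transition probability matrix
#'
#' Closed-form transition kernel of the two-state continuous-time Markov
#' chain with gain rate `q01` (0 to 1) and loss rate `q10` (1 to 0), over an
#' elapsed time `t` (branch length, Myr). With `s = q01 + q10`:
#' \deqn{P(t) = \frac{1}{s}\begin{pmatrix}
#'   q_{10} + q_{01}e^{-st} & q_{01}(1 - e^{-st}) \\
#'   q_{10}(1 - e^{-st})    & q_{01} + q_{10}e^{-st}
#' \end{pmatrix}}
#' Rows sum to 1 for every `t >= 0`; `t = 0` gives the identity.
#'
#' @param q01,q10 Strictly positive transition rates per Myr.
#' @param t Nonnegative elapsed time in Myr.
#' @return A 2x2 row-stochastic matrix with dimnames `c("0", "1")`; rows are
#'   the starting state, columns the ending state.
#' @export
mk_transition_matrix <- function(q01, q10, t) {
  check_rates(q01, q10)
  stopifnot(is.numeric(t), length(t) == 1L)
  if (t < 0) rlang::abort("elapsed time t must be nonnegative")
  s <- q01 + q10
  e <- exp(-s * t)
  m <- matrix(c(q10 + q01 * e, q01 * (1 - e),
                q10 * (1 - e), q01 + q10 * e) / s,
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  m
}

check_rates <- function(q01, q10) {
  stopifnot(is.numeric(q01), is.numeric(q10),
            length(q01) == 1L, length(q10) == 1L)
  if (!is.finite(q01) || !is.finite(q10) || q01 <= 0 || q10 <= 0) {
    rlang::abort("rates q01 and q10 must be strictly positive and finite")
  }
  invisible(NULL)
}

root_prior_probs <- function(root_prior, q01, q10) {
  root_prior <- match.arg(root_prior, c("equal", "stationary"))
  if (root_prior == "equal") c(0.5, 0.5) else c(q10, q01) / (q01 + q10)
}

# Precompute the postorder machinery for a tree once, so repeated likelihood
# evaluations during optimisation only touch flat vectors.
tree_pruning_data <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) rlang::abort("tree must have branch lengths")
  if (any(tree$edge.length < 0)) rlang::abort("negative branch lengths")
  tre <- ape::reorder.phylo(tree, "postorder")
  list(
    parent = tre$edge[, 1L],
    child = tre$edge[, 2L],
    elen = tre$edge.length,
    n_tip = length(tre$tip.label),
    n_node = tre$Nnode,
    root = length(tre$tip.label) + 1L,
    tip_label = tre$tip.label
  )
}

# Down (postorder) pass of Felsenstein pruning. Returns per-node conditional
# likelihoods normalised node-wise (underflow-safe) plus the accumulated log
# scaler and the total log-likelihood under the given root prior.
prune_down <- function(pd, states, q01, q10, root_prior = "equal") {
  n_all <- pd$n_tip + pd$n_node
  L0 <- numeric(n_all)
  L1 <- numeric(n_all)
  L0[seq_len(pd$n_tip)] <- 1 - states
  L1[seq_len(pd$n_tip)] <- states
  L0[(pd$n_tip + 1L):n_all] <- 1
  L1[(pd$n_tip + 1L):n_all] <- 1
  s <- q01 + q10
  log_scale <- 0
  parent <- pd$parent; child <- pd$child; elen <- pd$elen
  for (i in seq_along(parent)) {
    p <- parent[i]; ch <- child[i]
    e <- exp(-s * elen[i])
    c0 <- L0[ch]; c1 <- L1[ch]
    m <- max(c0, c1)
    if (m <= 0) {
      # impossible configuration below this node under these states
      return(list(L0 = L0, L1 = L1, loglik = -Inf, log_scale = -Inf))
    }
    c0 <- c0 / m; c1 <- c1 / m
    log_scale <- log_scale + log(m)
    # message child -> parent through P(t)
    L0[p] <- L0[p] * ((q10 + q01 * e) * c0 + q01 * (1 - e) * c1) / s
    L1[p] <- L1[p] * (q10 * (1 - e) * c0 + (q01 + q10 * e) * c1) / s
  }
  pi <- root_prior_probs(root_prior, q01, q10)
  lik_root <- pi[1L] * L0[pd$root] + pi[2L] * L1[pd$root]
  loglik <- if (lik_root > 0) log(lik_root) + log_scale else -Inf
  list(L0 = L0, L1 = L1, loglik = loglik, log_scale = log_scale)
}

#' Log-likelihood of a binary trait under the two-state Mk model
#'
#' Computes the probability of the observed tip states by Felsenstein's
#' pruning algorithm (a postorder dynamic program over per-state partial
#' likelihoods), with node-wise rescaling against underflow. Polytomies are
#' evaluated natively and zero-length branches use the identity kernel. Root
#' partials are combined with either a flat prior on the two states
#' (`"equal"`, the default) or the stationary distribution of the rates
#' (`"stationary"`).
#'
#' @param tree A rooted `phylo` object with branch lengths in Myr.
#' @param trait Tip states: a tibble `(species, fd_present)` as produced by
#'   [build_trait_vector()], or a named 0/1 vector covering every tip.
#' @inheritParams mk_transition_matrix
#' @param root_prior `"equal"` or `"stationary"`.
#' @return The log-likelihood (a single number, `<= 0`).
#' @export
mk_loglik <- function(tree, trait, q01, q10, root_prior = "equal") {
  check_rates(q01, q10)
  pd <- tree_pruning_data(tree)
  states <- as_trait_vector(trait, list(tip.label = pd$tip_label))
  prune_down(pd, states, q01, q10, root_prior)$loglik
}

#' AIC and BIC from a log-likelihood
#'
#' `aic = -2 logL + 2k` and `bic = -2 logL + k log(n)`, with the number of
#' tips as the effective sample size `n` — the convention under which the
#' two criteria differ by exactly `k (log n - 2)`.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of free rate parameters (1 for ER, 2 for ARD).
#' @param n_tips Number of tips in the tree.
#' @return A tibble with columns `aic` and `bic`.
#' @export
information_criteria <- function(loglik, k, n_tips) {
  stopifnot(k >= 1, n_tips >= 2)
  tibble::tibble(aic = -2 * loglik + 2 * k,
                 bic = -2 * loglik + k * log(n_tips))
}

#' Fit a two-state Mk model by maximum likelihood
#'
#' Fits either the equal-rates model (ER, one rate `q01 = q10`) or the
#' all-rates-different model (ARD, separate gain and loss rates) to a binary
#' tip trait. Optimisation runs in log-rate space within
#' `[1e-8, 1e3]` per Myr, from one deterministic start (the parsimony-flavour
#' guess of one expected change over the whole tree length) plus `n_starts -
#' 1` log-uniform random restarts; for ARD the ER optimum is added as a
#' further start, which guarantees `logL(ARD) >= logL(ER)`. Monomorphic
#' traits push an estimate to the rate bound; the fit is returned with
#' `boundary = TRUE` rather than erroring.
#'
#' @inheritParams mk_loglik
#' @param model `"ARD"` or `"ER"`.
#' @param n_starts Total number of optimiser starts (>= 1).
#' @param rate_bounds Length-2 positive bounds on each rate, per Myr.
#' @return An object of class `mk_fit`: rates, `loglik`, `k`, `n_tips`,
#'   `aic`, `bic`, `root_prior`, `model`, `boundary` flag and per-start
#'   convergence diagnostics. Use [generics::tidy()] for the rate estimates
#'   and [generics::glance()] for the one-row model summary.
#' @export
fit_mk <- function(tree, trait, model = c("ARD", "ER"),
                   root_prior = "equal", n_starts = 10L,
                   rate_bounds = c(1e-8, 1e3)) {
  model <- match.arg(model)
  root_prior <- match.arg(root_prior, c("equal", "stationary"))
  stopifnot(length(rate_bounds) == 2L, all(rate_bounds > 0),
            rate_bounds[1L] < rate_bounds[2L], n_starts >= 1L)
  pd <- tree_pruning_data(tree)
  if (pd$n_tip < 2L) rlang::abort("need at least 2 tips")
  states <- as_trait_vector(trait, list(tip.label = pd$tip_label))
  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])

  negll <- if (model == "ER") {
    function(lq) -prune_down(pd, states, exp(lq[1L]), exp(lq[1L]),
                             root_prior)$loglik
  } else {
    function(lq) -prune_down(pd, states, exp(lq[1L]), exp(lq[2L]),
                             root_prior)$loglik
  }

  # one expected change across the summed branch lengths: a scale-aware start
  q0 <- max(rate_bounds[1L] * 10, min(rate_bounds[2L] / 10,
                                      1 / sum(pd$elen)))
  npar <- if (model == "ER") 1L else 2L
  starts <- list(rep(log(q0), npar))
  if (n_starts > 1L) {
    extra <- matrix(stats::runif((n_starts - 1L) * npar,
                                 min = log(1e-4), max = log(1e2)),
                    ncol = npar)
    starts <- c(starts, lapply(seq_len(nrow(extra)), function(i) extra[i, ]))
  }
  er_fit <- NULL
  if (model == "ARD") {
    er_fit <- fit_mk(tree, states, model = "ER", root_prior = root_prior,
                     n_starts = n_starts, rate_bounds = rate_bounds)
    starts <- c(starts, list(rep(log(er_fit$rates[["q01"]]), 2L)))
  }

  runs <- lapply(starts, function(st) {
    fit <- tryCatch(
      stats::nlminb(st, negll, lower = lb, upper = ub,
                    control = list(rel.tol = 1e-10, abs.tol = 1e-12)),
      error = function(e) NULL)
    fit
  })
  runs <- Filter(Negate(is.null), runs)
  ok <- vapply(runs, function(f) is.finite(f$objective), logical(1L))
  runs <- runs[ok]
  if (length(runs) == 0L) {
    rlang::abort("Mk optimisation failed to converge from every start")
  }
  objs <- vapply(runs, `[[`, numeric(1L), "objective")
  best <- runs[[which.min(objs)]]
  lq <- best$par
  rates <- if (model == "ER") {
    c(q01 = exp(lq[1L]), q10 = exp(lq[1L]))
  } else {
    c(q01 = exp(lq[1L]), q10 = exp(lq[2L]))
  }
  loglik <- -best$objective
  k <- npar
  ic <- information_criteria(loglik, k, pd$n_tip)
  tol_b <- 1e-3   # log-rate units: within 0.1% of a bound counts as pinned
  boundary <- any(lq <= lb + tol_b | lq >= ub - tol_b) ||
    length(unique(states)) == 1L
  out <- list(
    rates = rates,
    model = model,
    loglik = loglik,
    k = k,
    n_tips = pd$n_tip,
    aic = ic$aic,
    bic = ic$bic,
    root_prior = root_prior,
    boundary = boundary,
    rate_bounds = rate_bounds,
    convergence = tibble::tibble(
      start = seq_along(objs),
      loglik = -objs,
      converged = vapply(runs, function(f) f$convergence == 0L, logical(1L))
    ),
    tree = tree,
    states = states
  )
  class(out) <- "mk_fit"
  out
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Two-state Mk fit (%s, root prior: %s)\n", x$model,
              x$root_prior))
  cat(sprintf("  q01 (gain/Myr) = %.6g   q10 (loss/Myr) = %.6g\n",
              x$rates[["q01"]], x$rates[["q10"]]))
  cat(sprintf("  logL = %.4f   AIC = %.2f   BIC = %.2f   (k = %d, n = %d)\n",
              x$loglik, x$aic, x$bic, x$k, x$n_tips))
  if (x$boundary) cat("  note: a rate estimate sits at the optimisation bound\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(term = c("q01", "q10"),
                 estimate = unname(x$rates),
                 rate_of = c("FD gain (0 to 1)", "FD loss (1 to 0)"))
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, AIC = x$aic,
                 BIC = x$bic, k = x$k, n_tips = x$n_tips,
                 root_prior = x$root_prior, boundary = x$boundary)
}

#' Compare ER and ARD Mk fits by AIC and BIC
#'
#' @param ... `mk_fit` objects (typically one ER and one ARD fit on the same
#'   tree and trait).
#' @return A tibble of one row per fit with `delta_aic` / `delta_bic`
#'   relative to the best score; the nested-model identity
#'   `delta_bic - delta_aic = (k2 - k1)(log n - 2)` holds exactly between any
#'   two fits on the same tree.
#' @export
compare_mk_fits <- function(...) {
  fits <- list(...)
  stopifnot(all(vapply(fits, inherits, logical(1L), "mk_fit")))
  out <- dplyr::bind_rows(lapply(fits, glance.mk_fit))
  out |>
    dplyr::mutate(delta_aic = .data$AIC - min(.data$AIC),
                  delta_bic = .data$BIC - min(.data$BIC)) |>
    dplyr::arrange(.data$AIC)
}
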