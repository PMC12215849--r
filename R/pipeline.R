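round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Dataset-level category counts and percentages
#'
#' Tabulates classified calls into the six categories plus two derived rows:
#' `ANY_COMBINATION` (FD + DF + FxD + other combinations, i.e. every call of
#' at least two distinguishable notes) and `TOTAL`. Percentages are of the
#' total call count, rounded half-up to one decimal.
#'
#' @param calls A call-level data frame with a `category` column.
#' @return A tibble `(category, n_calls, percent)`. An empty input yields
#'   zero counts with `percent = 0` and attribute `empty = TRUE`.
#' @examples
#' calls <- tibble::tibble(category = c("FD", "FD", "SINGLE"))
#' summarize_counts(calls)
#' @export
summarize_counts <- function(calls) {
  stopifnot(is.data.frame(calls), "category" %in% names(calls))
  cats <- factor(as.character(calls$category), levels = call_categories)
  if (anyNA(cats)) rlang::abort("calls contain categories outside the six-way taxonomy")
  n <- as.integer(table(cats))
  total <- sum(n)
  combo <- sum(n[match(c("FD", "DF", "FXD", "OTHER_COMBINATION"),
                       call_categories)])
  out <- tibble::tibble(
    category = c(call_categories, "ANY_COMBINATION", "TOTAL"),
    n_calls = c(n, combo, total),
    percent = if (total > 0) {
      round_half_up(100 * c(n, combo, total) / total, 1L)
    } else {
      rep(0, length(call_categories) + 2L)
    }
  )
  if (total == 0L) attr(out, "empty") <- TRUE
  out
}

#' Run the full FD call-combination analysis
#'
#' End-to-end driver: segment (when raw notes are given) and classify calls,
#' apply the FD-consistency criterion, map the binary trait onto the tree,
#' fit ER and ARD Mk models, compare them by AIC/BIC, reconstruct marginal
#' ancestral states under the AIC-best model, report the focal ancestor's
#' probability of using the FD combination, and optionally run robustness
#' experiments. Any stage failure aborts with a stage-tagged message. Given
#' the same inputs and seed the report is identical between runs.
#'
#' @param tree A rooted `phylo` with branch lengths in Myr.
#' @param notes A note-level table (see [segment_calls()]); either `notes`
#'   or `calls` must be supplied.
#' @param calls Alternatively, an already classified call-level table.
#' @param gap_threshold Segmentation threshold in seconds (`NULL` =
#'   estimate).
#' @inheritParams fd_consistency
#' @param root_prior Root prior for all fits and reconstructions.
#' @param clade_tips Tips defining the focal ancestor (default: all tips).
#' @param robustness A list of [robustness_config()] objects to run under
#'   the AIC-selected settings (default none).
#' @param n_starts Optimiser starts for the baseline fits.
#' @return A list of class `fd_analysis` with elements `counts`,
#'   `consistency`, `trait`, `fit_er`, `fit_ard`, `model_comparison`,
#'   `best_model`, `asr`, `ancestor_probability`, `robustness`, and `config`
#'   (all parameters plus a hash).
#' @export
run_fd_analysis <- function(tree, notes = NULL, calls = NULL,
                            gap_threshold = NULL, min_calls = 5L,
                            min_prop = 0.5, root_prior = "equal",
                            clade_tips = NULL, robustness = list(),
                            n_starts = 10L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("[stage: ", name, "] ", conditionMessage(e)))
    })
  }
  stage("inputs", {
    stopifnot(inherits(tree, "phylo"))
    if (is.null(notes) && is.null(calls)) {
      rlang::abort("supply either a note-level or a call-level table")
    }
  })
  if (is.null(calls)) {
    calls <- stage("segmentation+classification", {
      segment_calls(notes, gap_threshold) |> classify_calls()
    })
  }
  counts <- stage("counts", summarize_counts(calls))
  consistency <- stage("consistency", fd_consistency(calls, min_calls,
                                                     min_prop))
  trait <- stage("trait", build_trait_vector(consistency, tree))
  fit_er <- stage("fit ER", fit_mk(tree, trait, model = "ER",
                                   root_prior = root_prior,
                                   n_starts = n_starts))
  fit_ard <- stage("fit ARD", fit_mk(tree, trait, model = "ARD",
                                     root_prior = root_prior,
                                     n_starts = n_starts))
  comparison <- compare_mk_fits(fit_er, fit_ard)
  best <- comparison$model[1L]
  best_fit <- if (best == "ARD") fit_ard else fit_er
  asr <- stage("ancestral reconstruction", asr_marginal(fit = best_fit))
  if (is.null(clade_tips)) clade_tips <- tree$tip.label
  anc_p <- stage("ancestor probability", ancestor_probability(asr, clade_tips))
  rob <- stage("robustness", {
    lapply(robustness, function(cfg) {
      robustness_experiment(tree, calls, cfg, clade_tips = clade_tips,
                            min_calls = min_calls, min_prop = min_prop,
                            root_prior = root_prior)
    })
  })
  config <- list(gap_threshold = gap_threshold, min_calls = min_calls,
                 min_prop = min_prop, root_prior = root_prior,
                 clade_tips = clade_tips, n_starts = n_starts,
                 n_tips = length(tree$tip.label),
                 robustness = lapply(robustness, unclass))
  config$hash <- rlang::hash(config)
  structure(list(
    counts = counts, consistency = consistency, trait = trait,
    fit_er = fit_er, fit_ard = fit_ard, model_comparison = comparison,
    best_model = best, asr = asr, ancestor_probability = anc_p,
    robustness = rob, config = config, calls = calls, tree = tree
  ), class = "fd_analysis")
}

#' @export
print.fd_analysis <- function(x, ...) {
  cat("FD call-combination analysis\n")
  cat(sprintf("  %d tips, %d calls, %d FD-consistent species\n",
              x$config$n_tips, x$counts$n_calls[x$counts$category == "TOTAL"],
              sum(x$trait$fd_present)))
  cat(sprintf("  model selected by AIC: %s (dAIC to %s = %.2f)\n",
              x$best_model, x$model_comparison$model[2L],
              x$model_comparison$delta_aic[2L]))
  r <- x$fit_ard$rates
  cat(sprintf("  ARD rates: gain q01 = %.4g, loss q10 = %.4g (loss/gain = %.2f)\n",
              r[["q01"]], r[["q10"]], r[["q10"]] / r[["q01"]]))
  cat(sprintf("  P(FD at focal ancestor) = %.4f\n", x$ancestor_probability))
  for (rb in x$robustness) {
    cat(sprintf("  robustness %s: %.3f of %d sims above %.2f\n",
                rb$config$scheme, rb$fraction_above_threshold,
                rb$config$n_sims, rb$config$prob_threshold))
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (counts, consistency verdicts, fits, model
#' comparison, ancestral probabilities, robustness summaries, config hash)
#' plus TSVs of the consistency table, the trait, and the per-node
#' reconstruction. Output is deterministic: rerunning the same analysis
#' object produces byte-identical files.
#'
#' @param x An `fd_analysis` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to `report.json`.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "fd_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    schema_version = "1.0",
    config = x$config,
    counts = x$counts,
    consistency = dplyr::select(x$consistency, -"qualifying_recordings"),
    trait = x$trait,
    fits = list(ER = glance(x$fit_er), ARD = glance(x$fit_ard)),
    rates = list(ER = tidy(x$fit_er), ARD = tidy(x$fit_ard)),
    model_comparison = x$model_comparison,
    best_model = x$best_model,
    ancestor_probability = x$ancestor_probability,
    asr = tibble::as_tibble(unclass(x$asr)),
    robustness = lapply(x$robustness, glance)
  )
  path <- file.path(dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_tsv <- function(d, f) {
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(dplyr::select(x$consistency, -"qualifying_recordings"),
            "consistency.tsv")
  write_tsv(x$trait, "trait.tsv")
  write_tsv(tibble::as_tibble(unclass(x$asr)), "asr.tsv")
  invisible(path)
}
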