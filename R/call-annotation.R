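#' Call categories
#'
#' The six-way taxonomy used throughout the package. Every classified call
#' belongs to exactly one category, so per-recording category counts always
#' sum to the number of calls.
#'
#' * `SINGLE` — a call of one note.
#' * `REPEATED` — one note type repeated (length >= 2, all labels identical).
#' * `FD` — one homogeneous block of F notes followed by one block of D notes
#'   (e.g. FDDDD, FFFFFFD).
#' * `DF` — the mirror order: one D block followed by one F block.
#' * `FXD` — F and D notes only, with more than one alternation between
#'   blocks (three or more blocks, e.g. FFFDDDFF).
#' * `OTHER_COMBINATION` — two or more distinct note types where at least one
#'   is neither F nor D.
#'
#' @format A character vector of the six category names, in canonical order.
#' @export
call_categories <- c("SINGLE", "REPEATED", "FD", "DF", "FXD",
                     "OTHER_COMBINATION")

note_labels_known <- c("F", "D", "OTHER")

validate_notes <- function(notes, need_timing = FALSE) {
  stopifnot(is.data.frame(notes))
  required <- c("species", "recording_id", "label")
  missing <- setdiff(required, names(notes))
  if (length(missing) > 0L) {
    rlang::abort(paste0("note table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(notes$label), note_labels_known)
  if (length(bad) > 0L) {
    rlang::abort(paste0("unknown note label(s): ", paste(bad, collapse = ", "),
                        " (expected F, D or OTHER)"))
  }
  if (need_timing) {
    if (!all(c("onset_s", "offset_s") %in% names(notes)) ||
        anyNA(notes$onset_s) || anyNA(notes$offset_s)) {
      rlang::abort("segmentation needs complete onset_s and offset_s columns")
    }
    if (any(notes$offset_s <= notes$onset_s)) {
      rlang::abort(paste0("notes with non-positive duration found ",
                          "(offset_s <= onset_s); fix the annotations before ",
                          "segmenting"))
    }
    unsorted <- notes |>
      dplyr::group_by(.data$species, .data$recording_id) |>
      dplyr::summarise(ok = !is.unsorted(.data$onset_s), .groups = "drop")
    if (!all(unsorted$ok)) {
      rlang::abort("notes must be sorted by onset_s within each recording")
    }
  }
  invisible(notes)
}

#' Segment annotated notes into calls by silence gaps
#'
#' Notes belong to the same call when the silence separating them is short;
#' a new call starts whenever the gap from the previous note's offset to the
#' next note's onset exceeds `gap_threshold`. This mirrors how annotated
#' Parid recordings are segmented: silences within a call combination are an
#' order of magnitude shorter (about 0.09 s) than silences between calls
#' (about 2.55 s), so a single threshold separates the two regimes.
#'
#' @param notes A data frame of annotated notes with columns `species`,
#'   `recording_id`, `label` (one of `"F"`, `"D"`, `"OTHER"`), `onset_s`,
#'   `offset_s`, sorted by onset within each recording.
#' @param gap_threshold Silence duration in seconds above which two
#'   consecutive notes fall in different calls. Default `NULL` estimates it
#'   from the pooled gap distribution via [estimate_gap_threshold()].
#' @return The input tibble with an added `call_id` column (an integer index
#'   of the call within its recording); note order is preserved and every
#'   note belongs to exactly one call.
#' @seealso [classify_calls()], [estimate_gap_threshold()]
#' @examples
#' notes <- tibble::tibble(
#'   species = "parus_major", recording_id = "r1",
#'   label = c("F", "D", "D", "F", "F"),
#'   onset_s  = c(0, 0.2, 0.4, 3.5, 3.7),
#'   offset_s = c(0.1, 0.3, 0.5, 3.6, 3.8)
#' )
#' segment_calls(notes, gap_threshold = 0.5)
#' @export
segment_calls <- function(notes, gap_threshold = NULL) {
  validate_notes(notes, need_timing = TRUE)
  if (is.null(gap_threshold)) {
    gap_threshold <- estimate_gap_threshold(notes)
  }
  stopifnot(is.numeric(gap_threshold), length(gap_threshold) == 1L,
            gap_threshold > 0)
  notes |>
    dplyr::group_by(.data$species, .data$recording_id) |>
    dplyr::mutate(
      gap_before = .data$onset_s - dplyr::lag(.data$offset_s),
      call_id = cumsum(dplyr::coalesce(.data$gap_before > gap_threshold,
                                       TRUE))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"gap_before") |>
    tibble::as_tibble()
}

#' Estimate the call-separating silence threshold from gap durations
#'
#' Finds the largest jump in the sorted log silence-gap sequence and returns
#' the geometric midpoint of the two gaps flanking that jump. When intra- and
#' inter-call silences form two well-separated modes (the situation reported
#' for Parid recordings, where the two distributions never overlap), this
#' lands strictly between them. When the gaps are essentially constant there
#' is nothing to split: the function returns the maximum gap plus a small
#' margin, warns, and marks the result with `attr(x, "degenerate") = TRUE`.
#'
#' @inheritParams segment_calls
#' @return A single positive number (seconds) suitable as `gap_threshold`
#'   for [segment_calls()].
#' @export
estimate_gap_threshold <- function(notes) {
  validate_notes(notes, need_timing = TRUE)
  gaps <- notes |>
    dplyr::group_by(.data$species, .data$recording_id) |>
    dplyr::mutate(gap = .data$onset_s - dplyr::lag(.data$offset_s)) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$gap)
  gaps <- gaps[!is.na(gaps) & gaps > 0]
  if (length(gaps) < 2L) {
    rlang::abort(paste0("need at least two positive silence gaps to estimate ",
                        "a threshold; supply gap_threshold explicitly"))
  }
  lg <- sort(log(gaps))
  jumps <- diff(lg)
  rel_spread <- diff(range(lg))
  if (max(jumps) <= 1e-8 || rel_spread < 1e-6) {
    out <- max(gaps) * 1.001 + 1e-6
    attr(out, "degenerate") <- TRUE
    rlang::warn("gap distribution is unimodal/constant; returning max gap + margin")
    return(out)
  }
  i <- which.max(jumps)
  out <- exp((lg[i] + lg[i + 1L]) / 2)
  attr(out, "degenerate") <- FALSE
  out
}

classify_label_seq <- function(labels) {
  n <- length(labels)
  if (n == 0L) rlang::abort("cannot classify an empty call")
  bad <- setdiff(unique(labels), note_labels_known)
  if (length(bad) > 0L) {
    rlang::abort(paste0("unknown note label(s): ", paste(bad, collapse = ", ")))
  }
  if (n == 1L) return("SINGLE")
  runs <- rle(labels)$values
  if (length(runs) == 1L) return("REPEATED")
  if (any(labels == "OTHER")) return("OTHER_COMBINATION")
  # only F and D remain, with >= 2 blocks
  if (length(runs) == 2L) {
    if (identical(runs, c("F", "D"))) return("FD")
    return("DF")
  }
  "FXD"
}

#' Classify a single call from its ordered note labels
#'
#' Applies the strict block definition of the FD combination: a call is `FD`
#' only when it consists of exactly one homogeneous block of F notes followed
#' by one block of D notes — so FDDDD and FFFFFFD are FD calls, while
#' FFFDDDFF (more than one alternation, `FXD`) and DDDDF (reversed order,
#' `DF`) are not. Block lengths are irrelevant. Calls mixing F or D with any
#' other note type are `OTHER_COMBINATION`; see [call_categories].
#'
#' @param labels Character vector of ordered note labels
#'   (`"F"`, `"D"`, `"OTHER"`), length >= 1.
#' @return A single category name.
#' @examples
#' classify_call(c("F", "D", "D", "D", "D"))   # "FD"
#' classify_call(c("D", "D", "D", "D", "F"))   # "DF"
#' classify_call(c("F", "F", "D", "D", "F"))   # "FXD"
#' @export
classify_call <- function(labels) {
  classify_label_seq(as.character(labels))
}

#' Classify every segmented call in a note table
#'
#' @param notes A segmented note table (output of [segment_calls()], or any
#'   note table already carrying a `call_id` column).
#' @return A call-level tibble with one row per call: `species`,
#'   `recording_id`, `call_id`, `n_notes`, `labels` (collapsed label string)
#'   and `category` (a factor over [call_categories]).
#' @export
classify_calls <- function(notes) {
  validate_notes(notes)
  if (!"call_id" %in% names(notes)) {
    rlang::abort("notes carry no call_id; run segment_calls() first")
  }
  notes |>
    dplyr::group_by(.data$species, .data$recording_id, .data$call_id) |>
    dplyr::summarise(
      n_notes = dplyr::n(),
      labels = paste(.data$label, collapse = ""),
      category = classify_label_seq(.data$label),
      .groups = "drop"
    ) |>
    dplyr::mutate(category = factor(.data$category, levels = call_categories))
}

#' Label notes as F or D from acoustic features
#'
#' Optional helper for unlabelled notes: splits notes into two clusters on
#' (peak frequency, bandwidth) and calls the cluster with the higher mean
#' frequency *and* the smaller mean bandwidth "F", the other "D" — frequency
#' and bandwidth being the two features with stable F/D differences across
#' Parids. The rule is deliberately conservative: if the two cues disagree
#' (the higher-frequency cluster is also the broader-band one), or the
#' features admit no two-cluster split, every note is labelled `OTHER` rather
#' than guessed.
#'
#' @param notes A data frame with numeric columns `peak_freq_hz` and
#'   `bandwidth_hz`, complete for every row.
#' @return The input tibble with a `label` column filled in.
#' @export
label_notes <- function(notes) {
  stopifnot(is.data.frame(notes))
  if (!all(c("peak_freq_hz", "bandwidth_hz") %in% names(notes)) ||
      anyNA(notes$peak_freq_hz) || anyNA(notes$bandwidth_hz)) {
    rlang::abort(paste0("complete peak_freq_hz and bandwidth_hz are required; ",
                        "otherwise supply note labels directly"))
  }
  if (nrow(notes) < 2L) rlang::abort("need at least 2 notes to label")
  feats <- cbind(notes$peak_freq_hz, notes$bandwidth_hz)
  notes <- tibble::as_tibble(notes)
  if (nrow(unique(feats)) < 2L) {
    notes$label <- "OTHER"
    return(notes)
  }
  scaled <- apply(feats, 2L, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  km <- stats::kmeans(scaled, centers = 2L, nstart = 10L)
  freq_means <- tapply(notes$peak_freq_hz, km$cluster, mean)
  bw_means <- tapply(notes$bandwidth_hz, km$cluster, mean)
  hi <- which.max(freq_means)
  lo <- setdiff(c(1L, 2L), hi)
  if (bw_means[[hi]] < bw_means[[lo]]) {
    notes$label <- ifelse(km$cluster == hi, "F", "D")
  } else {
    notes$label <- "OTHER"   # cues disagree: refuse to call F/D
  }
  notes
}

per_recording_profile <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("species", "recording_id", "category") %in% names(calls)))
  calls |>
    dplyr::count(.data$species, .data$recording_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (cat in setdiff(call_categories, names(d))) d[[cat]] <- 0L
      d
    })() |>
    dplyr::mutate(n_calls = rowSums(dplyr::pick(dplyr::all_of(call_categories))))
}

#' Per-species FD- and DF-consistency verdicts
#'
#' A species is *FD-consistent* when at least one of its recordings contains
#' at least `min_calls` calls of which strictly more than `min_prop` are FD
#' calls. The criterion demands not just the presence of FD calls, but
#' consistent use within one context (one recording). The mirror DF criterion
#' is computed identically from DF counts. The FD:DF count ratio is reported
#' as a diagnostic of order preference but does not enter the verdict.
#'
#' @param calls A call-level data frame with columns `species`,
#'   `recording_id`, `category` (e.g. from [classify_calls()]).
#' @param min_calls Minimum number of calls a recording must contain to
#'   qualify (inclusive; default 5).
#' @param min_prop Proportion of FD calls a qualifying recording must exceed
#'   (strict; default 0.5, i.e. a recording at exactly 50% FD fails).
#' @return A tibble with one row per species: aggregate counts (`n_calls`,
#'   `n_fd`, `n_df`), `n_recordings`, the verdicts `passes_fd` / `passes_df`,
#'   `n_qualifying_fd` (recordings meeting the FD criterion),
#'   `qualifying_recordings` (list column of their ids), and `fd_df_ratio`
#'   (`Inf` when DF = 0 < FD; `NaN` when both are 0).
#' @export
fd_consistency <- function(calls, min_calls = 5L, min_prop = 0.5) {
  prof <- per_recording_profile(calls) |>
    dplyr::mutate(
      qualifies_fd = .data$n_calls >= min_calls &
        .data$FD / .data$n_calls > min_prop,
      qualifies_df = .data$n_calls >= min_calls &
        .data$DF / .data$n_calls > min_prop
    )
  prof |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_recordings = dplyr::n(),
      n_calls = sum(.data$n_calls),
      n_fd = sum(.data$FD),
      n_df = sum(.data$DF),
      n_qualifying_fd = sum(.data$qualifies_fd),
      n_qualifying_df = sum(.data$qualifies_df),
      qualifying_recordings = list(.data$recording_id[.data$qualifies_fd]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      passes_fd = .data$n_qualifying_fd > 0L,
      passes_df = .data$n_qualifying_df > 0L,
      fd_df_ratio = order_preference_ratio(.data$n_fd, .data$n_df)
    )
}

#' FD over DF order-preference ratio
#'
#' Ratio of aggregate FD to DF call counts for a species. FD-consistent
#' Parids typically produce at least 5 times as many FD as DF calls,
#' confirming that note order, not just note content, is stable.
#'
#' @param n_fd,n_df Nonnegative counts (vectorised).
#' @return `n_fd / n_df`; `Inf` when `n_df` is 0 and `n_fd` positive; `NaN`
#'   when both are 0 (no order information at all).
#' @examples
#' order_preference_ratio(46, 9)   # Azure tit: 5.11
#' @export
order_preference_ratio <- function(n_fd, n_df) {
  stopifnot(all(n_fd >= 0), all(n_df >= 0))
  n_fd / n_df   # 0/0 is NaN, x/0 is Inf: exactly the documented sentinels
}

#' Build the binary FD-presence trait over the tips of a phylogeny
#'
#' Maps consistency verdicts onto a tree's tip set. Species present in the
#' call data but absent from the tree are dropped with a warning (as when a
#' species cannot be located in the synthetic phylogeny); a tree tip with no
#' call data is an error — states are never silently imputed.
#'
#' @param consistency A per-species tibble from [fd_consistency()] (or any
#'   data frame with `species` and a logical/binary `passes_fd`).
#' @param tree A rooted `phylo` object, or a character vector of tip labels.
#' @return A tibble `(species, fd_present)` in tip-label order, with
#'   `fd_present` in {0, 1}.
#' @export
build_trait_vector <- function(consistency, tree) {
  stopifnot(is.data.frame(consistency),
            all(c("species", "passes_fd") %in% names(consistency)))
  tips <- if (inherits(tree, "phylo")) tree$tip.label else as.character(tree)
  extra <- setdiff(consistency$species, tips)
  if (length(extra) > 0L) {
    rlang::warn(paste0("dropping species absent from the tree: ",
                       paste(extra, collapse = ", ")))
  }
  missing <- setdiff(tips, consistency$species)
  if (length(missing) > 0L) {
    rlang::abort(paste0("tree tip(s) with no call data: ",
                        paste(missing, collapse = ", ")))
  }
  idx <- match(tips, consistency$species)
  tibble::tibble(species = tips,
                 fd_present = as.integer(consistency$passes_fd[idx]))
}

# Accepts a (species, state) data frame or a named 0/1 vector; returns a
# named integer vector aligned to the tree's tip labels.
as_trait_vector <- function(trait, tree) {
  tips <- tree$tip.label
  if (is.data.frame(trait)) {
    state_col <- intersect(c("fd_present", "state"), names(trait))[1]
    if (is.na(state_col) || !"species" %in% names(trait)) {
      rlang::abort("trait table needs columns species and fd_present/state")
    }
    x <- stats::setNames(trait[[state_col]], trait$species)
  } else {
    x <- trait
  }
  if (is.null(names(x))) rlang::abort("trait vector must be named by species")
  missing <- setdiff(tips, names(x))
  if (length(missing) > 0L) {
    rlang::abort(paste0("no trait state for tip(s): ",
                        paste(missing, collapse = ", ")))
  }
  x <- x[tips]
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    rlang::abort("trait states must be binary 0/1 with no missing values")
  }
  stats::setNames(as.integer(x), tips)
}
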