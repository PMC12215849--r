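test_that("segmentation splits note streams at long silences", {
  notes <- notes_from_gaps(c("F", "F", "D", "F", "D"),
                           gaps = c(0.1, 0.1, 3.0, 0.1))
  seg <- segment_calls(notes, gap_threshold = 0.5)
  expect_equal(seg$call_id, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(as.integer(table(seg$call_id)), c(3L, 2L))

  single <- notes_from_gaps("F", gaps = numeric(0))
  expect_equal(segment_calls(single, gap_threshold = 0.5)$call_id, 1L)

  sparse <- notes_from_gaps(c("F", "D", "F"), gaps = c(2, 2))
  expect_equal(segment_calls(sparse, gap_threshold = 0.5)$call_id, 1:3)
})

test_that("segmentation rejects malformed annotations", {
  bad_dur <- notes_from_gaps(c("F", "D"), gaps = 0.1)
  bad_dur$offset_s[2] <- bad_dur$onset_s[2] - 0.05
  expect_error(segment_calls(bad_dur, 0.5), "duration")

  unsorted <- notes_from_gaps(c("F", "D", "F"), gaps = c(0.1, 0.1))
  unsorted <- unsorted[c(2, 1, 3), ]
  expect_error(segment_calls(unsorted, 0.5), "sorted")

  bad_label <- notes_from_gaps(c("F", "Z"), gaps = 0.1)
  expect_error(segment_calls(bad_label, 0.5), "unknown note label")
})

test_that("gap threshold lands between the intra- and inter-call modes", {
  set.seed(42)
  gaps <- c(rlnorm(25, log(0.09), 0.3), rlnorm(25, log(2.55), 0.3))
  notes <- notes_from_gaps(rep("F", 51), gaps = sample(gaps))
  th <- estimate_gap_threshold(notes)
  expect_gt(th, 0.2)
  expect_lt(th, 2.5)

  two <- notes_from_gaps(rep("F", 3), gaps = c(0.1, 3.0))
  th2 <- estimate_gap_threshold(two)
  expect_gt(th2, 0.1)
  expect_lt(th2, 3.0)
})

test_that("gap threshold handles degenerate and tiny inputs", {
  const <- notes_from_gaps(rep("F", 5), gaps = rep(0.2, 4))
  expect_warning(th <- estimate_gap_threshold(const), "unimodal")
  expect_gt(th, 0.2)
  expect_true(attr(th, "degenerate"))

  one_gap <- notes_from_gaps(c("F", "D"), gaps = 0.1)
  expect_error(estimate_gap_threshold(one_gap), "explicit")
})

test_that("call classification follows the strict two-block FD definition", {
  expect_equal(classify_call(strsplit("FDDDD", "")[[1]]), "FD")
  expect_equal(classify_call(strsplit("FFFFFFD", "")[[1]]), "FD")
  expect_equal(classify_call(strsplit("FFFDDDFF", "")[[1]]), "FXD")
  expect_equal(classify_call(strsplit("DDDDF", "")[[1]]), "DF")
  expect_equal(classify_call("F"), "SINGLE")
  expect_equal(classify_call(c("D", "D", "D")), "REPEATED")
  expect_equal(classify_call(c("F", "OTHER")), "OTHER_COMBINATION")
  expect_equal(classify_call(c("OTHER", "OTHER")), "REPEATED")
  expect_error(classify_call(character(0)), "empty")
  expect_error(classify_call(c("F", "Q")), "unknown")
})

test_that("classification agrees with a regular-expression oracle", {
  set.seed(7)
  for (i in 1:500) {
    labs <- sample(c("F", "D", "OTHER"), sample(1:12, 1), replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
    expect_equal(classify_call(labs), regex_classify(labs),
                 info = paste(labs, collapse = ","))
  }
})

test_that("reversing a two-block FD call gives DF", {
  set.seed(8)
  for (i in 1:100) {
    labs <- c(rep("F", sample(1:5, 1)), rep("D", sample(1:5, 1)))
    expect_equal(classify_call(labs), "FD")
    expect_equal(classify_call(rev(labs)), "DF")
  }
})

test_that("note labelling from acoustics is conservative", {
  sep <- tibble::tibble(
    peak_freq_hz = c(rep(7000, 3), rep(3500, 4)),
    bandwidth_hz = c(rep(1000, 3), rep(5000, 4)))
  expect_equal(label_notes(sep)$label, c(rep("F", 3), rep("D", 4)))

  flat <- tibble::tibble(peak_freq_hz = rep(5000, 4),
                         bandwidth_hz = rep(2000, 4))
  expect_equal(unique(label_notes(flat)$label), "OTHER")

  disagree <- tibble::tibble(
    peak_freq_hz = c(rep(7000, 3), rep(3500, 3)),
    bandwidth_hz = c(rep(5000, 3), rep(1000, 3)))
  expect_equal(unique(label_notes(disagree)$label), "OTHER")

  expect_error(label_notes(tibble::tibble(peak_freq_hz = 1:3)), "supply")
})

test_that("FD-consistency applies the >=5-call and strict >50% boundaries", {
  pass <- calls_from_counts("sp", list(c(FD = 4, SINGLE = 2)))
  expect_true(fd_consistency(pass)$passes_fd)

  few <- calls_from_counts("sp", list(c(FD = 4)))
  expect_false(fd_consistency(few)$passes_fd)

  tie <- calls_from_counts("sp", list(c(FD = 3, SINGLE = 3)))
  expect_false(fd_consistency(tie)$passes_fd)

  # one qualifying recording among several non-qualifying ones suffices
  mixed <- calls_from_counts("sp", list(c(FD = 1, SINGLE = 9),
                                        c(FD = 5, SINGLE = 1)))
  res <- fd_consistency(mixed)
  expect_true(res$passes_fd)
  expect_equal(res$qualifying_recordings[[1]], "r2")
  expect_false(res$passes_df)
})

test_that("adding FD calls to a qualifying recording never revokes a pass", {
  set.seed(9)
  for (i in 1:25) {
    n_fd <- sample(3:10, 1); n_other <- sample(0:4, 1)
    base <- calls_from_counts("sp", list(c(FD = n_fd, SINGLE = n_other)))
    if (!fd_consistency(base)$passes_fd) next
    more <- calls_from_counts("sp", list(c(FD = n_fd + sample(1:5, 1),
                                           SINGLE = n_other)))
    expect_true(fd_consistency(more)$passes_fd)
  }
})

test_that("category counts partition every recording's calls", {
  study <- simulate_study(n_tips = 6, seed = 21,
                          call_config = list(recordings_per_species = 3))
  calls <- classify_calls(segment_calls(study$notes))
  prof <- calls |> dplyr::count(species, recording_id, category) |>
    dplyr::group_by(species, recording_id) |> dplyr::summarise(n = sum(n), .groups = "drop")
  tot <- calls |> dplyr::count(species, recording_id)
  expect_equal(prof$n, tot$n)
})

test_that("order-preference ratio uses the documented sentinels", {
  expect_equal(order_preference_ratio(46, 9), 46 / 9)
  expect_gte(order_preference_ratio(46, 9), 5)
  expect_identical(order_preference_ratio(10, 0), Inf)
  expect_true(is.nan(order_preference_ratio(0, 0)))
  expect_error(order_preference_ratio(-1, 2))
})

test_that("trait vector covers tree tips exactly, dropping extra species", {
  cons <- tibble::tibble(species = c("A", "B", "C"),
                         passes_fd = c(TRUE, FALSE, FALSE))
  expect_equal(build_trait_vector(cons, c("A", "B", "C"))$fd_present,
               c(1L, 0L, 0L))

  cons2 <- dplyr::bind_rows(cons,
                            tibble::tibble(species = "D", passes_fd = TRUE))
  expect_warning(tv <- build_trait_vector(cons2, c("A", "B", "C")),
                 "absent from the tree")
  expect_equal(tv$species, c("A", "B", "C"))

  expect_error(build_trait_vector(cons, c("A", "B", "C", "E")),
               "no call data")
})
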