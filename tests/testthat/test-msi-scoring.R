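test_that("peak calling reports maxima, separation, and ladder heights", {
  panel <- tiny_panel()
  loc <- panel[[1]]
  wt <- loc$product_size_wt

  single <- detect_peaks(simulate_electropherogram(loc, setNames(1, wt),
                                                   stutter_rate = 0,
                                                   noise_sd = 0))
  expect_identical(nrow(single), 1L)
  expect_identical(single$size_bp, wt)
  expect_equal(single$relative_height, 1)

  two <- detect_peaks(simulate_electropherogram(
    loc, setNames(c(0.5, 0.5), c(wt, wt - 4)), stutter_rate = 0,
    noise_sd = 0), min_separation_bp = 2)
  expect_identical(two$size_bp, c(wt - 4L, wt))
  expect_equal(two$height[1], two$height[2])

  # ladder-formula oracle: on a decaying stutter ladder only the allele peak
  # is a local maximum, so thresholds cannot resurrect the stutter points
  ladder <- simulate_electropherogram(loc, setNames(1, wt),
                                      stutter_rate = 0.1,
                                      stutter_decay = 0.5, noise_sd = 0)
  pk <- detect_peaks(ladder, min_rel_height = 0.2)
  expect_identical(pk$size_bp, wt)
  pk_low <- detect_peaks(ladder, min_rel_height = 0.02,
                         min_separation_bp = 1)
  expect_identical(pk_low$size_bp, wt)

  empty <- detect_peaks(electropherogram(1:10, rep(0, 10)))
  expect_identical(nrow(empty), 0L)
  expect_error(detect_peaks(ladder, min_rel_height = 0), "min_rel_height")
})

test_that("marker scoring implements the shift / new-peak disjunction", {
  panel <- tiny_panel()
  loc <- panel[[1]]
  wt <- loc$product_size_wt
  peaks_at <- function(fr) detect_peaks(simulate_electropherogram(
    loc, fr, stutter_rate = 0, noise_sd = 0))
  ctl <- peaks_at(setNames(1, wt))

  shifted <- score_marker(peaks_at(setNames(1, wt - 4)), ctl)
  expect_true(shifted$unstable)
  expect_identical(shifted$shift_magnitude, 4L)

  same <- score_marker(ctl, ctl)
  expect_false(same$unstable)
  expect_identical(same$shift_magnitude, 0L)
  expect_length(same$new_peak_sizes, 0)

  # dominant peak unchanged but an extra allele appears: new-peak rule fires
  extra <- score_marker(peaks_at(setNames(c(0.7, 0.3), c(wt, wt - 6))), ctl)
  expect_true(extra$unstable)
  expect_identical(extra$shift_magnitude, 0L)
  expect_identical(extra$new_peak_sizes, wt - 6L)

  # a minor peak 1 bp below a dominant one at <50% height is stutter,
  # not a new allele
  stutter_peaks <- data.frame(size_bp = c(wt - 1L, wt),
                              height = c(0.3, 1),
                              relative_height = c(0.3, 1))
  class(stutter_peaks) <- c("peak_set", "data.frame")
  sc <- score_marker(stutter_peaks, ctl)
  expect_false(sc$unstable)
  # the same peak above 50% is treated as a real new allele
  real_peaks <- stutter_peaks
  real_peaks$height[1] <- 0.8
  expect_true(score_marker(real_peaks, ctl)$unstable)

  # empty sample peak set is unevaluable, empty control an error
  none <- data.frame(size_bp = integer(0), height = numeric(0),
                     relative_height = numeric(0))
  expect_true(is.na(score_marker(none, ctl)$unstable))
  expect_error(score_marker(ctl, none), "control")
})

test_that("MSI-H requires instability at two or more markers", {
  mk <- function(unstable) data.frame(
    marker_id = paste0("m", seq_along(unstable)), unstable = unstable,
    shift_magnitude = ifelse(is.na(unstable), NA_integer_,
                             ifelse(unstable, 3L, 0L)))
  expect_identical(classify_msi(mk(rep(TRUE, 7)))$classification, "MSI-H")
  expect_identical(classify_msi(mk(c(TRUE, rep(FALSE, 6))))$classification,
                   "MSS")
  expect_identical(classify_msi(mk(c(TRUE, TRUE, rep(FALSE, 5))))$classification,
                   "MSI-H")
  expect_identical(classify_msi(mk(rep(FALSE, 7)))$classification, "MSS")
  # unevaluable markers are excluded from the count
  expect_identical(classify_msi(mk(c(TRUE, TRUE, rep(NA, 5))))$classification,
                   "MSI-H")
  expect_identical(classify_msi(mk(c(TRUE, rep(NA, 6))))$classification,
                   "unevaluable")
})

test_that("panel scoring matches planted instability exactly without noise", {
  panel <- demo_panel()
  n_markers <- sum(vapply(panel, `[[`, FALSE, "is_msi_marker"))
  set.seed(404)
  for (rep_i in 1:25) {
    k <- sample(0:n_markers, 1)
    unstable_idx <- sort(sample(n_markers, k))
    shifts <- sample(1:12, n_markers, replace = TRUE)
    tp <- make_trace_panel(panel, unstable_idx, shifts, noise_sd = 0,
                           seed = rep_i)
    rep_out <- score_msi_sample(tp$sample, tp$control)
    expect_identical(rep_out$n_unstable, as.integer(k))
    expect_identical(rep_out$classification, if (k >= 2) "MSI-H" else "MSS")
    got_shift <- rep_out$markers$shift_magnitude
    want <- integer(n_markers)
    want[unstable_idx] <- shifts[unstable_idx]
    expect_identical(got_shift, want)
  }
})

test_that("scoring a control against itself is stable; larger shifts stay unstable", {
  panel <- demo_panel()
  markers <- panel[vapply(panel, `[[`, FALSE, "is_msi_marker")]
  loc <- markers[[2]]
  ctl <- detect_peaks(simulate_electropherogram(
    loc, setNames(1, loc$product_size_wt), 0.02, 0.3, 0))
  expect_false(score_marker(ctl, ctl)$unstable)
  for (sh in 1:10) {
    pk <- detect_peaks(simulate_electropherogram(
      loc, setNames(c(0.7, 0.3),
                    c(loc$product_size_wt - sh, loc$product_size_wt)),
      0.02, 0.3, 0))
    sc <- score_marker(pk, ctl)
    expect_true(sc$unstable)
    expect_identical(sc$shift_magnitude, as.integer(sh))
  }
})

test_that("profile comparison reports per-marker deltas and the trend flag", {
  parental <- c(`mU12235-A24` = 4, `mL24372-A27` = 6, mBat64 = 25)
  passaged <- c(`mU12235-A24` = 6, `mL24372-A27` = 11, mBat64 = 37)
  cmp <- compare_profiles(parental, passaged)
  expect_identical(cmp$delta, c(2, 5, 12))
  expect_true(attr(cmp, "increased_instability"))

  same <- compare_profiles(parental, parental)
  expect_identical(same$delta, c(0, 0, 0))
  expect_false(attr(same, "increased_instability"))

  set.seed(5)
  for (i in 1:10) {
    a <- setNames(sample(0:30, 5), letters[1:5])
    b <- setNames(sample(0:30, 5), letters[1:5])
    cmp <- compare_profiles(a, b)
    expect_identical(cmp$delta, unname(b - a))
  }
  expect_error(compare_profiles(c(x = 1), c(y = 2)), "share no markers")
})
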