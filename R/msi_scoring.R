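#' Electropherogram container
#'
#' A fragment-analysis trace: fluorescence intensity on a strictly
#' increasing 1-bp fragment-size grid.
#'
#' @param size_bp Integer sizes in bp (consecutive, step 1).
#' @param intensity Non-negative intensities.
#' @param sample_id,marker_id Labels.
#' @return A data frame of class `electropherogram`.
#' @export
electropherogram <- function(size_bp, intensity, sample_id = NA_character_,
                             marker_id = NA_character_) {
  size_bp <- as.integer(size_bp)
  if (length(size_bp) != length(intensity))
    stopf("size_bp and intensity lengths differ")
  if (length(size_bp) > 1 && any(diff(size_bp) != 1L))
    stopf("sizes must be strictly increasing on a 1-bp grid")
  if (any(intensity < 0)) stopf("intensities must be >= 0")
  structure(data.frame(size_bp = size_bp, intensity = intensity),
            sample_id = sample_id, marker_id = marker_id,
            class = c("electropherogram", "data.frame"))
}

#' Call peaks in a fragment trace
#'
#' Local maxima with height at least `min_rel_height` of the trace maximum,
#' thinned so kept peaks are at least `min_separation_bp` apart (taller
#' peaks win; at equal height the smaller size wins, and equal-height peaks
#' far enough apart are both kept).
#'
#' @param trace An [electropherogram()].
#' @param min_rel_height Minimum height as a fraction of the maximum
#'   intensity (in `(0, 1)`).
#' @param min_separation_bp Minimum distance between reported peaks.
#' @return A `peak_set` data frame: `size_bp`, `height`, `relative_height`,
#'   sorted by size. Empty for an all-zero trace.
#' @export
detect_peaks <- function(trace, min_rel_height = 0.10,
                         min_separation_bp = 2L) {
  if (min_rel_height <= 0 || min_rel_height >= 1)
    stopf("min_rel_height must be in (0, 1)")
  y <- trace$intensity
  s <- trace$size_bp
  empty <- data.frame(size_bp = integer(0), height = numeric(0),
                      relative_height = numeric(0))
  class(empty) <- c("peak_set", "data.frame")
  n <- length(y)
  if (n == 0 || all(y == 0)) return(empty)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  cand <- which(y > 0 & y >= left & y >= right & y >= min_rel_height * max(y))
  if (!length(cand)) return(empty)
  ord <- cand[order(-y[cand], s[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(s[i] - s[kept]) >= min_separation_bp))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  out <- data.frame(size_bp = s[kept], height = y[kept],
                    relative_height = y[kept] / max(y))
  class(out) <- c("peak_set", "data.frame")
  out
}

dominant_peak <- function(peaks) {
  # tallest; ties broken toward the smaller size (deletions dominate
  # slippage in MMR-deficient tumours)
  i <- order(-peaks$height, peaks$size_bp)[1]
  peaks$size_bp[i]
}

#' Score one MSI marker against its matched control
#'
#' A marker is unstable when the sample's dominant product is shifted by at
#' least 1 bp from the control's dominant product, or when the sample shows
#' peaks absent from the control ("new peaks"). The reported
#' `shift_magnitude` is the absolute dominant-peak shift in bp (the "mN"
#' notation: m4 means a 4-bp shift). Minor peaks within
#' `stutter_window_bp` below a taller sample peak and under
#' `stutter_rel_height` of its height are treated as the PCR stutter ladder,
#' not as new peaks.
#'
#' @param sample_peaks,control_peaks `peak_set`s from [detect_peaks()]; the
#'   control set must be non-empty.
#' @param tolerance_bp Matching tolerance for the new-peak rule (0 on the
#'   simulator's integer grid; use 1 for noisy real traces).
#' @param stutter_window_bp,stutter_rel_height Stutter-suppression rule
#'   (set `stutter_window_bp = 0` to disable).
#' @return A list: `unstable` (logical, `NA` when the sample peak set is
#'   empty and the marker unevaluable), `shift_magnitude`,
#'   `new_peak_sizes`.
#' @export
score_marker <- function(sample_peaks, control_peaks, tolerance_bp = 0L,
                         stutter_window_bp = 2L, stutter_rel_height = 0.5) {
  if (!nrow(control_peaks)) stopf("control peak set is empty")
  if (!nrow(sample_peaks)) {
    return(list(unstable = NA, shift_magnitude = NA_integer_,
                new_peak_sizes = integer(0)))
  }
  dom_s <- dominant_peak(sample_peaks)
  dom_c <- dominant_peak(control_peaks)
  shift <- abs(dom_s - dom_c)
  is_new <- vapply(seq_len(nrow(sample_peaks)), function(i) {
    min(abs(sample_peaks$size_bp[i] - control_peaks$size_bp)) > tolerance_bp
  }, FALSE)
  if (stutter_window_bp > 0 && any(is_new)) {
    for (i in which(is_new)) {
      sz <- sample_peaks$size_bp[i]
      h <- sample_peaks$height[i]
      taller <- sample_peaks$size_bp > sz &
        sample_peaks$size_bp <= sz + stutter_window_bp &
        sample_peaks$height > h
      if (any(taller) &&
          h < stutter_rel_height * max(sample_peaks$height[taller]))
        is_new[i] <- FALSE
    }
  }
  new_sizes <- sample_peaks$size_bp[is_new]
  list(unstable = shift >= 1L || length(new_sizes) > 0,
       shift_magnitude = as.integer(shift),
       new_peak_sizes = as.integer(new_sizes))
}

#' Classify MSI status over a marker panel
#'
#' MSI-high (MSI-H) means instability at two or more markers;
#' microsatellite stable (MSS) means instability at one marker or none.
#' Markers whose score is `NA` (unevaluable) are excluded from the count; if
#' fewer than `min_evaluable` markers remain the sample is unevaluable.
#'
#' @param marker_results Either a data frame with columns `marker_id`,
#'   `unstable`, `shift_magnitude`, or a named list of [score_marker()]
#'   results.
#' @param sample_id Label for the report.
#' @param min_evaluable Minimum evaluable markers for a classification.
#' @return An `msi_report` list: `sample_id`, `markers` (data frame),
#'   `n_evaluable`, `n_unstable`, `classification`
#'   (`"MSI-H"`, `"MSS"`, or `"unevaluable"`).
#' @export
classify_msi <- function(marker_results, sample_id = NA_character_,
                         min_evaluable = 2L) {
  if (!is.data.frame(marker_results)) {
    marker_results <- data.frame(
      marker_id = names(marker_results),
      unstable = vapply(marker_results, function(r) {
        if (is.na(r$unstable)) NA else isTRUE(r$unstable)
      }, NA),
      shift_magnitude = vapply(marker_results, function(r)
        as.integer(r$shift_magnitude), NA_integer_),
      row.names = NULL)
  }
  evaluable <- !is.na(marker_results$unstable)
  n_eval <- sum(evaluable)
  n_unstable <- sum(marker_results$unstable[evaluable])
  classification <- if (n_eval < min_evaluable) "unevaluable"
  else if (n_unstable >= 2L) "MSI-H" else "MSS"
  structure(list(sample_id = sample_id, markers = marker_results,
                 n_evaluable = n_eval, n_unstable = n_unstable,
                 classification = classification),
            class = "msi_report")
}

#' @export
print.msi_report <- function(x, ...) {
  cat(sprintf("<msi_report %s: %s (%d/%d markers unstable)>\n", x$sample_id,
              x$classification, x$n_unstable, x$n_evaluable))
  invisible(x)
}

#' Score a full marker panel for one sample
#'
#' Peak-calls each sample trace and its matched control trace, scores every
#' marker, and classifies the sample.
#'
#' @param sample_traces,control_traces Named lists of [electropherogram()]s
#'   keyed by marker; markers are matched by name.
#' @param min_rel_height,min_separation_bp Passed to [detect_peaks()].
#' @param tolerance_bp,stutter_window_bp,stutter_rel_height Passed to
#'   [score_marker()].
#' @param sample_id Report label.
#' @return An `msi_report`.
#' @export
score_msi_sample <- function(sample_traces, control_traces,
                             min_rel_height = 0.10, min_separation_bp = 2L,
                             tolerance_bp = 0L, stutter_window_bp = 2L,
                             stutter_rel_height = 0.5,
                             sample_id = NA_character_) {
  markers <- intersect(names(sample_traces), names(control_traces))
  if (!length(markers)) stopf("no shared markers between sample and control")
  res <- lapply(markers, function(m) {
    score_marker(detect_peaks(sample_traces[[m]], min_rel_height,
                              min_separation_bp),
                 detect_peaks(control_traces[[m]], min_rel_height,
                              min_separation_bp),
                 tolerance_bp, stutter_window_bp, stutter_rel_height)
  })
  names(res) <- markers
  classify_msi(res, sample_id = sample_id)
}

#' Compare two shift profiles
#'
#' Tabulates the per-marker shift-magnitude difference between two MSI
#' profiles (for example a parental organoid line and its serially
#' transplanted derivative) and flags increased instability when the median
#' difference is positive.
#'
#' @param profile_a,profile_b Named numeric vectors of shift magnitudes in
#'   bp, or `msi_report` objects.
#' @return Data frame `marker`, `m_a`, `m_b`, `delta` (`m_b - m_a`) with
#'   attribute `increased_instability`.
#' @export
#' @examples
#' cmp <- compare_profiles(c(A = 4, B = 6, C = 25), c(A = 6, B = 11, C = 37))
#' cmp$delta
#' attr(cmp, "increased_instability")
compare_profiles <- function(profile_a, profile_b) {
  as_shifts <- function(p) {
    if (inherits(p, "msi_report"))
      setNames(p$markers$shift_magnitude, p$markers$marker_id)
    else p
  }
  a <- as_shifts(profile_a)
  b <- as_shifts(profile_b)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stopf("profiles share no markers")
  out <- data.frame(marker = shared, m_a = unname(a[shared]),
                    m_b = unname(b[shared]),
                    delta = unname(b[shared] - a[shared]), row.names = NULL)
  attr(out, "increased_instability") <- median(out$delta) > 0
  out
}
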