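# Peak detection and oscillation classification.

# Topographic prominence of local maxima in a numeric vector.
# Returns indices of strict local maxima (plateaus collapse to their
# first frame) and their prominences: peak height minus the higher of
# the two valley floors separating it from the nearest higher terrain
# (or the signal edge).
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # collapse plateaus: compare to previous distinct value and next
  # distinct value
  up <- c(FALSE, diff(x) > 0)
  down_next <- c(diff(x) < 0, FALSE)
  # carry plateau state: a frame is a peak start if the last nonzero
  # step was up and the next nonzero step is down
  last_dir <- numeric(n)
  d <- 0
  for (i in 2:n) {
    step <- x[i] - x[i - 1]
    if (step != 0) d <- sign(step)
    last_dir[i] <- d
  }
  next_dir <- numeric(n)
  d <- 0
  for (i in (n - 1):1) {
    step <- x[i + 1] - x[i]
    if (step != 0) d <- sign(step)
    next_dir[i] <- d
  }
  which(last_dir == 1 & next_dir == -1)
}

.prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until higher terrain or edge; valley floor = min en route
    left <- x[seq_len(p - 1)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(x[(max(higher_l) + 1):(p - 1)]) else
      min(left, h)
    right <- x[(p + 1):length(x)]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else
      min(right, h)
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Detect peaks in a calcium trace
#'
#' Local maxima filtered by topographic prominence and a minimum
#' separation.  The default prominence threshold is `k_mad` times a
#' robust noise estimate, the median absolute deviation of the
#' first-differenced trace divided by sqrt(2).  First differencing
#' (rather than detrending the trace itself) keeps slow oscillations
#' out of the noise estimate, so a strong oscillator does not raise its
#' own detection threshold.  Peaks closer than `min_separation_s` to a
#' larger accepted peak are dropped.  Missing frames (e.g. the blanked
#' drug-addition frame) are bridged by linear interpolation before
#' detection.
#'
#' @param time_s,intensity Trace vectors (at least 10 frames).
#' @param min_prominence Absolute prominence cutoff; overrides the
#'   MAD-based default when supplied.
#' @param k_mad Multiplier of the noise MAD.
#' @param min_separation_s Minimum peak separation in seconds (default
#'   3 frames).
#' @return Tibble: time_s, value, prominence, one row per peak.
#' @export
detect_peaks <- function(time_s, intensity, min_prominence = NULL,
                         k_mad = 8, min_separation_s = NULL) {
  ok <- is.finite(intensity)
  if (!any(ok)) abort("all-missing trace")
  if (length(intensity) < 10) abort("need at least 10 frames")
  x <- intensity
  if (any(!ok)) {
    x[!ok] <- stats::approx(time_s[ok], intensity[ok], xout = time_s[!ok],
                            rule = 2)$y
  }
  dt <- median(diff(time_s))
  if (is.null(min_separation_s)) min_separation_s <- 3 * dt
  if (is.null(min_prominence)) {
    min_prominence <- k_mad * mad(diff(x)) / sqrt(2)
  }
  peaks <- .local_maxima(x)
  if (!length(peaks)) {
    return(tibble::tibble(time_s = numeric(), value = numeric(),
                          prominence = numeric()))
  }
  prom <- .prominence(x, peaks)
  keep <- prom > min_prominence & prom > 0
  peaks <- peaks[keep]; prom <- prom[keep]
  if (length(peaks) > 1) {
    # greedy by height: suppress smaller peaks within the separation
    ord <- order(-x[peaks])
    accepted <- integer(0)
    for (i in ord) {
      if (!length(accepted) ||
          all(abs(time_s[peaks[i]] - time_s[peaks[accepted]]) >= min_separation_s)) {
        accepted <- c(accepted, i)
      }
    }
    sel <- sort(accepted)
    peaks <- peaks[sel]; prom <- prom[sel]
  }
  tibble::tibble(time_s = time_s[peaks], value = x[peaks], prominence = prom)
}

#' Classify oscillatory activity per ROI and window
#'
#' Splits each trace at the drug-addition time into a baseline and a
#' post-drug window, counts detected peaks per window and calls a
#' window oscillatory (the presence mark) when it holds at least
#' `min_peaks` peaks (absence otherwise).
#'
#' @param traces Long tibble (roi_id, time_s, intensity); pass ratio
#'   traces for dual-channel data.
#' @param drug_time_s Drug-addition time splitting the windows.
#' @param min_peaks Minimum peaks for an oscillatory call.
#' @param ... Passed to [detect_peaks()].
#' @return Tibble: roi_id, window (`"baseline"`/`"post_drug"`),
#'   n_peaks, oscillatory.
#' @export
classify_oscillation <- function(traces, drug_time_s, min_peaks = 2, ...) {
  traces <- tibble::as_tibble(traces)
  traces$window <- ifelse(traces$time_s < drug_time_s, "baseline", "post_drug")
  traces |>
    dplyr::group_by(.data$roi_id, .data$window) |>
    dplyr::summarise(
      n_peaks = nrow(detect_peaks(.data$time_s, .data$intensity, ...)),
      .groups = "drop") |>
    dplyr::mutate(oscillatory = .data$n_peaks >= min_peaks)
}

#' Summarize oscillation calls per line/experiment
#'
#' Fraction of ROIs oscillatory per window, optionally per grouping
#' column (cell line, experiment).  When an `experiment` column is
#' present with at least two experiments, a paired two-tailed t-test
#' compares per-experiment oscillating fractions between baseline and
#' post-drug windows.
#'
#' @param calls Output of [classify_oscillation()], optionally with
#'   extra grouping columns joined on.
#' @param group Optional grouping column name (e.g. `"cell_line"`).
#' @return List with `fractions` (tibble) and `paired_p` (NA without
#'   replicate experiments).
#' @export
summarize_oscillation <- function(calls, group = NULL) {
  keys <- c(group, if ("experiment" %in% names(calls)) "experiment", "window")
  fractions <- calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_rois = dplyr::n(),
                     fraction_oscillating = mean(.data$oscillatory),
                     .groups = "drop")
  paired_p <- NA_real_
  if ("experiment" %in% names(calls)) {
    wide <- tidyr::pivot_wider(
      fractions[, c(intersect("experiment", names(fractions)), "window",
                    "fraction_oscillating")],
      names_from = "window", values_from = "fraction_oscillating")
    if (nrow(wide) >= 2 && all(c("baseline", "post_drug") %in% names(wide)) &&
        sd(wide$post_drug - wide$baseline) > 0) {
      paired_p <- t.test(wide$post_drug, wide$baseline, paired = TRUE)$p.value
    }
  }
  list(fractions = fractions, paired_p = paired_p)
}
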