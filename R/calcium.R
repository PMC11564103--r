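# Calcium trace analysis: plate-level kinetics and single-cell
# ratiometric imaging.

#' Plate-assay fold change in calcium signal
#'
#' Mean signal over the post-treatment response window divided by the
#' mean over the pre-treatment baseline window.  The defaults are the
#' kinetic-assay convention: response 400-600 s, baseline 200-300 s.
#'
#' @param time_s,intensity Trace vectors (seconds, arbitrary units).
#' @param baseline_window,response_window Length-2 windows in seconds
#'   (inclusive).
#' @return Fold change; `NA` with a warning when the baseline mean is
#'   not positive.
#' @export
flipr_fold_change <- function(time_s, intensity,
                              baseline_window = c(200, 300),
                              response_window = c(400, 600)) {
  in_win <- function(w) time_s >= w[1] & time_s <= w[2]
  if (!any(in_win(baseline_window)) || !any(in_win(response_window))) {
    abort("window outside the trace's time span")
  }
  base <- mean(intensity[in_win(baseline_window)], na.rm = TRUE)
  resp <- mean(intensity[in_win(response_window)], na.rm = TRUE)
  if (!is.finite(base) || base <= 0) {
    warn("baseline mean <= 0: fold change undefined")
    return(NA_real_)
  }
  resp / base
}

#' Background-correct and ratio dual-channel Fura-2 traces
#'
#' Per frame, the mean background-ROI intensity is subtracted from
#' every cell ROI in each channel.  The background floor is the lower
#' 1st percentile of corrected intensities across cells within the
#' first 30 s of imaging (per channel); ROIs with more than
#' `max_subfloor_frames` frames below the floor are excluded (strictly
#' more than 5 by default).  The ratiometric signal is corrected 340 /
#' corrected 380; the drug-addition frame is set to missing to rule out
#' perfusion artefacts, as are frames with a non-positive 380 signal.
#'
#' @param traces Long tibble (roi_id, time_s, channel, intensity) with
#'   channels `"340"`, `"380"` and `"background_340"`,
#'   `"background_380"`.
#' @param drug_time_s Time of drug addition (its frame becomes NA); use
#'   [detect_drug_frame()] when unknown.
#' @param max_subfloor_frames Exclusion cutoff on sub-floor frames.
#' @param floor_quantile Background-floor quantile.
#' @param floor_window_s Span (from t = 0) the floor is computed over.
#' @return List with `ratio` (tibble roi_id, time_s, ratio) for
#'   retained ROIs and `exclusions` (tibble roi_id, n_subfloor,
#'   excluded, reason).
#' @export
fura2_preprocess <- function(traces, drug_time_s = NULL,
                             max_subfloor_frames = 5,
                             floor_quantile = 0.01,
                             floor_window_s = 30) {
  traces <- tibble::as_tibble(traces)
  bg <- traces[grepl("^background_", traces$channel), ]
  if (nrow(bg) == 0) abort("no background ROIs present")
  cellt <- traces[traces$channel %in% c("340", "380"), ]
  bg_mean <- bg |>
    dplyr::mutate(channel = sub("background_", "", .data$channel)) |>
    dplyr::group_by(.data$time_s, .data$channel) |>
    dplyr::summarise(bg = mean(.data$intensity), .groups = "drop")
  corrected <- dplyr::left_join(cellt, bg_mean, by = c("time_s", "channel")) |>
    dplyr::mutate(corrected = .data$intensity - dplyr::coalesce(.data$bg, 0))

  early <- corrected[corrected$time_s <= floor_window_s, ]
  floors <- early |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(floor = quantile(.data$corrected, floor_quantile),
                     .groups = "drop")
  corrected <- dplyr::left_join(corrected, floors, by = "channel")
  subfloor <- corrected |>
    dplyr::group_by(.data$roi_id, .data$time_s) |>
    dplyr::summarise(sub = any(.data$corrected < .data$floor), .groups = "drop") |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(n_subfloor = sum(.data$sub), .groups = "drop")
  subfloor$excluded <- subfloor$n_subfloor > max_subfloor_frames
  subfloor$reason <- ifelse(subfloor$excluded,
                            sprintf("more than %d sub-floor frames",
                                    max_subfloor_frames),
                            NA_character_)

  wide <- corrected |>
    dplyr::select("roi_id", "time_s", "channel", "corrected") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "corrected",
                       names_prefix = "ch") |>
    dplyr::mutate(ratio = ifelse(.data$ch380 > 0,
                                 .data$ch340 / .data$ch380, NA_real_))
  if (!is.null(drug_time_s)) {
    times <- sort(unique(wide$time_s))
    drug_frame_time <- times[which.min(abs(times - drug_time_s))]
    wide$ratio[wide$time_s == drug_frame_time] <- NA_real_
  }
  keep <- subfloor$roi_id[!subfloor$excluded]
  list(ratio = wide[wide$roi_id %in% keep, c("roi_id", "time_s", "ratio")],
       exclusions = subfloor)
}

#' Locate the drug-addition frame from a population jump
#'
#' Finds the largest one-frame jump of the across-ROI median trace
#' within the search window (drug addition happened between 120 s and
#' 150 s in the imaging assay).  An explicitly known addition time
#' always takes precedence over detection.
#'
#' @param traces Long tibble (roi_id, time_s, intensity) of the traces
#'   to scan (single channel or precomputed ratios as `intensity`).
#' @param search_window_s Length-2 window the jump must fall in.
#' @return The time (s) of the first frame after the jump.
#' @export
detect_drug_frame <- function(traces, search_window_s = c(120, 150)) {
  med <- traces |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(m = median(.data$intensity, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(.data$time_s)
  jump <- diff(med$m)
  t_after <- med$time_s[-1]
  in_win <- t_after >= search_window_s[1] & t_after <= search_window_s[2]
  if (!any(in_win)) abort("search window outside the trace span")
  t_after[in_win][which.max(abs(jump[in_win]))]
}

#' Normalize a trace to its baseline
#'
#' `F0` is the mean over the baseline window (the full pre-drug span by
#' default); returns both `dff = (F - F0)/F0` and the
#' baseline-subtracted variant `f_sub = F - F0`.
#'
#' @param time_s,intensity Trace vectors.
#' @param drug_time_s Drug-addition time bounding the default baseline.
#' @param baseline_window Optional explicit window (seconds).
#' @return Tibble: time_s, intensity, dff, f_sub.
#' @export
normalize_trace <- function(time_s, intensity, drug_time_s = NULL,
                            baseline_window = NULL) {
  if (is.null(baseline_window)) {
    if (is.null(drug_time_s)) abort("need `drug_time_s` or `baseline_window`")
    sel <- time_s < drug_time_s  # full pre-drug span, drug frame excluded
  } else {
    sel <- time_s >= baseline_window[1] & time_s <= baseline_window[2]
  }
  f0 <- mean(intensity[sel], na.rm = TRUE)
  if (!is.finite(f0) || f0 <= 0) {
    warn("baseline F0 <= 0: dF/F0 undefined")
    return(tibble::tibble(time_s = time_s, intensity = intensity,
                          dff = NA_real_, f_sub = intensity - f0))
  }
  tibble::tibble(time_s = time_s, intensity = intensity,
                 dff = (intensity - f0) / f0, f_sub = intensity - f0)
}

#' Mean signal change after drug addition
#'
#' Mean over the `window_s` seconds after drug addition minus the mean
#' over the `window_s` seconds before it (120 s windows by default).
#'
#' @param time_s,intensity Trace vectors.
#' @param drug_time_s Drug-addition time.
#' @param window_s Averaging window length (seconds).
#' @return Post-minus-pre mean difference.
#' @export
mean_drug_response <- function(time_s, intensity, drug_time_s, window_s = 120) {
  tmin <- min(time_s); tmax <- max(time_s)
  if (drug_time_s - window_s < tmin || drug_time_s + window_s > tmax) {
    abort(sprintf("trace does not cover %g s on both sides of drug addition", window_s))
  }
  pre <- time_s >= drug_time_s - window_s & time_s < drug_time_s
  post <- time_s > drug_time_s & time_s <= drug_time_s + window_s
  mean(intensity[post], na.rm = TRUE) - mean(intensity[pre], na.rm = TRUE)
}
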