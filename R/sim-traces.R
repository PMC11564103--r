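#' Configuration for simulated calcium traces
#'
#' Emulates ratiometric single-cell calcium imaging: frames every
#' `frame_interval_s` seconds (2 s by default, matching the acquisition
#' rate of the imaging assay), a drug addition at `drug_frame` that adds
#' `drug_step` to every ROI, and a planted fraction of oscillating ROIs
#' whose latent signal is `baseline + amplitude * sin(2*pi*t/period +
#' phase)`; non-oscillators are flat.  Gaussian noise of `noise_sd` is
#' added per frame.  In dual-channel mode each ROI emits a 340 nm and a
#' 380 nm channel whose background-corrected ratio equals the latent
#' signal up to noise, plus `n_background_rois` background ROI pairs.
#'
#' @param n_rois Number of cell ROIs.
#' @param n_frames Frames per trace.
#' @param frame_interval_s Seconds between frames.
#' @param oscillator_fraction Probability that an ROI oscillates.
#' @param period_s Length-2 range oscillation periods are drawn from.
#' @param amplitude Length-2 range oscillation amplitudes are drawn from.
#' @param baseline Latent baseline level.
#' @param drug_frame Frame index (1-based) of drug addition.
#' @param drug_step Additive latent shift after drug addition.
#' @param noise_sd Gaussian noise standard deviation.
#' @param dual_channel Emit 340/380 channel pairs instead of a single
#'   `well` channel.
#' @param n_background_rois Background ROI pairs (dual-channel mode).
#' @param seed Integer master seed.
#' @return A list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(n_rois = 100,
                             n_frames = 300,
                             frame_interval_s = 2,
                             oscillator_fraction = 0.5,
                             period_s = c(40, 80),
                             amplitude = c(0.5, 1),
                             baseline = 2,
                             drug_frame = 65,
                             drug_step = 0.5,
                             noise_sd = 0.1,
                             dual_channel = FALSE,
                             n_background_rois = 5,
                             seed = 1L) {
  n_rois <- check_count(n_rois, "n_rois")
  n_frames <- check_count(n_frames, "n_frames", min = 2)
  frame_interval_s <- check_positive(frame_interval_s, "frame_interval_s")
  check_prob(oscillator_fraction, "oscillator_fraction")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  drug_frame <- check_count(drug_frame, "drug_frame")
  if (drug_frame >= n_frames) abort("`drug_frame` must be < `n_frames`")
  period_s <- sort(rep_len(period_s, 2))
  if (period_s[1] < 2 * frame_interval_s) {
    abort("undersampled oscillation: `period_s` must be at least 2 frame intervals")
  }
  structure(
    list(n_rois = n_rois, n_frames = n_frames,
         frame_interval_s = frame_interval_s,
         oscillator_fraction = oscillator_fraction, period_s = period_s,
         amplitude = sort(rep_len(amplitude, 2)), baseline = baseline,
         drug_frame = drug_frame, drug_step = drug_step,
         noise_sd = noise_sd, dual_channel = dual_channel,
         n_background_rois = check_count(n_background_rois, "n_background_rois", min = 0),
         seed = as.integer(seed)),
    class = "trace_sim_config"
  )
}

#' Simulate a set of calcium traces with planted oscillators
#'
#' @param config A [trace_sim_config()].
#' @return A list with `traces` (long tibble: roi_id, time_s, channel,
#'   intensity; channel is `"well"` or `"340"`/`"380"` plus
#'   `"background_340"`/`"background_380"`), `truth` (tibble: roi_id,
#'   oscillator, period_s, amplitude, post_drug_level) and `drug_time_s`.
#' @export
simulate_traces <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  t_s <- (seq_len(config$n_frames) - 1) * config$frame_interval_s
  drug_time <- t_s[config$drug_frame]
  step <- ifelse(seq_len(config$n_frames) > config$drug_frame, config$drug_step, 0)

  rois <- sprintf("roi%04d", seq_len(config$n_rois))
  out <- vector("list", config$n_rois)
  truth <- vector("list", config$n_rois)
  for (r in seq_len(config$n_rois)) {
    set.seed(substream_seed(config$seed, r))
    osc <- runif(1) < config$oscillator_fraction
    period <- runif(1, config$period_s[1], config$period_s[2])
    amp <- runif(1, config$amplitude[1], config$amplitude[2])
    phase <- runif(1, 0, 2 * pi)
    latent <- config$baseline + step +
      if (osc) amp * sin(2 * pi * t_s / period + phase) else 0
    if (config$dual_channel) {
      # 380 nm channel constant, 340 nm proportional to the latent
      # signal; per-channel noise and a shared additive background.
      # ROIs span a brightness gradient (dye loading varies across
      # cells), which the ratio cancels; the dimmest cells sit near the
      # cohort's background floor, as in real recordings.
      bright <- if (config$n_rois == 1) 1 else
        seq(1.3, 0.7, length.out = config$n_rois)[r]
      ch380 <- 400 * bright + rnorm(config$n_frames, sd = config$noise_sd * 100)
      ch340 <- latent * 400 * bright + rnorm(config$n_frames, sd = config$noise_sd * 100)
      out[[r]] <- tibble::tibble(
        roi_id = rois[r], time_s = rep(t_s, 2),
        channel = rep(c("340", "380"), each = config$n_frames),
        intensity = c(ch340 + 50, ch380 + 50)
      )
    } else {
      out[[r]] <- tibble::tibble(
        roi_id = rois[r], time_s = t_s, channel = "well",
        intensity = latent + rnorm(config$n_frames, sd = config$noise_sd)
      )
    }
    truth[[r]] <- tibble::tibble(
      roi_id = rois[r], oscillator = osc,
      period_s = if (osc) period else NA_real_,
      amplitude = if (osc) amp else NA_real_,
      post_drug_level = config$baseline + config$drug_step
    )
  }
  traces <- dplyr::bind_rows(out)
  if (config$dual_channel && config$n_background_rois > 0) {
    bg <- purrr::map_dfr(seq_len(config$n_background_rois), function(b) {
      set.seed(substream_seed(config$seed, config$n_rois + b))
      tibble::tibble(
        roi_id = sprintf("bg%02d", b), time_s = rep(t_s, 2),
        channel = rep(c("background_340", "background_380"),
                      each = config$n_frames),
        intensity = 50 + rnorm(2 * config$n_frames, sd = 2)
      )
    })
    traces <- dplyr::bind_rows(traces, bg)
  }
  list(traces = traces, truth = dplyr::bind_rows(truth), drug_time_s = drug_time)
}
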