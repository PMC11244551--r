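#' Feature-extraction configuration
#'
#' Tunable parameters of the per-point feature extractors. Defaults follow
#' common electro-anatomical practice; see the package vignette for the
#' rationale behind each value.
#'
#' @param lead_for_jpoint ECG lead used for J-point detection (default V2;
#'   any standard lead may be chosen when V2 quality is poor).
#' @param baseline_window_ms duration of the baseline segment ending at the
#'   QRS onset, used as the Uni-JEl reference (ms).
#' @param t_search_min_ms,t_search_max_ms T-wave search bounds after the
#'   depolarization fiducial for the Wyatt ARI (ms).
#' @param noise_rms_max_mv baseline RMS above which a trace is rejected as
#'   noise (mV).
#' @param derivative_smoothing_window_ms window of the local-linear
#'   (Savitzky-Golay order 1) derivative used for QRS fiducials; 3 samples
#'   minimum, which reduces to plain central differences.
#' @param t_smoothing_window_ms wider derivative window used only inside
#'   the T-wave search, where slopes are an order of magnitude gentler than
#'   in the QRS.
#' @param jpoint_deriv_frac fraction of the peak QRS derivative below which
#'   the ECG is considered iso-electric after the QRS.
#' @param jpoint_hold_ms time the derivative must stay below that fraction
#'   for the QRS offset to be accepted (ms).
#' @param qrs_pre_ms assumed QRS span before the J-point, used to anchor
#'   the baseline window when no QRS onset is supplied (ms).
#' @param v2_fiducial reference fiducial on the surface lead for activation
#'   time: `"min"` (amplitude minimum, the default) or `"dvdt_min"`
#'   (steepest negative slope).
#' @return A list of class `epm_config`.
#' @export
feature_config <- function(lead_for_jpoint = "V2",
                           baseline_window_ms = 40,
                           t_search_min_ms = 120,
                           t_search_max_ms = 450,
                           noise_rms_max_mv = 0.15,
                           derivative_smoothing_window_ms = 5,
                           t_smoothing_window_ms = 25,
                           jpoint_deriv_frac = 0.02,
                           jpoint_hold_ms = 20,
                           qrs_pre_ms = 80,
                           v2_fiducial = c("min", "dvdt_min")) {
  if (baseline_window_ms <= 0 || jpoint_hold_ms <= 0)
    stop("windows must be positive")
  if (t_search_min_ms >= t_search_max_ms)
    stop("t_search_min_ms must be < t_search_max_ms")
  structure(list(lead_for_jpoint = lead_for_jpoint,
                 baseline_window_ms = baseline_window_ms,
                 t_search_min_ms = t_search_min_ms,
                 t_search_max_ms = t_search_max_ms,
                 noise_rms_max_mv = noise_rms_max_mv,
                 derivative_smoothing_window_ms = derivative_smoothing_window_ms,
                 t_smoothing_window_ms = t_smoothing_window_ms,
                 jpoint_deriv_frac = jpoint_deriv_frac,
                 jpoint_hold_ms = jpoint_hold_ms,
                 qrs_pre_ms = qrs_pre_ms,
                 v2_fiducial = match.arg(v2_fiducial)),
            class = "epm_config")
}

# Smoothed derivative (mV/ms): local linear-regression slope over a centred
# window (Savitzky-Golay, order 1). window_ms <= 3 samples is exactly the
# central difference. Edges where the window does not fit are NA.
smoothed_derivative <- function(x, fs, window_ms) {
  n <- length(x)
  half <- max(1L, floor(window_ms * fs / 1000 / 2))
  k <- 2L * half + 1L
  if (k >= n) stop("derivative window exceeds trace length")
  i <- seq(-half, half)
  w <- i / sum(i^2) / (1000 / fs)      # slope per ms
  d <- stats::filter(x, rev(w), sides = 2)
  as.numeric(d)
}

# Earliest-sample argmin / argmax (which.min/which.max already take the
# first of tied values; NA-safe).
arg_extreme <- function(x, maximum = FALSE) {
  if (all(is.na(x))) stop("window contains no finite samples")
  if (maximum) which.max(x) else which.min(x)
}

ms_to_sample <- function(ms, fs) as.integer(round(ms * fs / 1000)) + 1L

#' Detect the ECG J-point (QRS offset)
#'
#' Derivative-threshold QRS-offset detector: the dominant QRS deflection is
#' located, the peak absolute (smoothed) derivative within the QRS is
#' measured, and the J-point is the first sample after the deflection where
#' the absolute derivative stays below `jpoint_deriv_frac` of that peak for
#' at least `jpoint_hold_ms`. The detector is deliberately simple and fully
#' determined by [feature_config()]; alternative detectors can be swapped
#' in by passing a function with the same signature wherever a J-point is
#' consumed.
#'
#' @param trace ECG lead trace (mV).
#' @param fs sampling rate (Hz).
#' @param config an [feature_config()].
#' @param search window (sample indices, length 2) inside which the QRS is
#'   sought; defaults to the whole trace.
#' @return J-point sample index (1-based).
#' @export
detect_jpoint <- function(trace, fs, config = feature_config(),
                          search = NULL) {
  n <- length(trace)
  if (is.null(search)) search <- c(1L, n)
  idx <- seq(max(1L, search[1]), min(n, search[2]))
  seg <- trace[idx]
  if (diff(range(seg)) < 1e-9) stop("no QRS detected (flat trace)")
  d <- abs(smoothed_derivative(trace, fs, config$derivative_smoothing_window_ms))
  peak <- idx[arg_extreme(abs(seg - stats::median(seg)), maximum = TRUE)]
  half_qrs <- ms_to_sample(60, fs) - 1L
  qrs_rng <- max(1L, peak - half_qrs):min(n, peak + half_qrs)
  dmax <- max(d[qrs_rng], na.rm = TRUE)
  if (!is.finite(dmax) || dmax < 1e-9) stop("no QRS detected (flat trace)")
  thr <- config$jpoint_deriv_frac * dmax
  hold <- ms_to_sample(config$jpoint_hold_ms, fs) - 1L
  below <- d < thr
  below[is.na(below)] <- FALSE
  i <- peak
  while (i + hold <= n) {
    if (all(below[i:(i + hold)])) return(i)
    i <- i + 1L
  }
  stop("no QRS offset found within the trace")
}

# QRS onset: mirror of detect_jpoint, scanning backwards from the dominant
# deflection. Used to anchor the Uni-JEl baseline window.
detect_qrs_onset <- function(trace, fs, config = feature_config(),
                             search = NULL) {
  n <- length(trace)
  if (is.null(search)) search <- c(1L, n)
  idx <- seq(max(1L, search[1]), min(n, search[2]))
  seg <- trace[idx]
  if (diff(range(seg)) < 1e-9) stop("no QRS detected (flat trace)")
  d <- abs(smoothed_derivative(trace, fs, config$derivative_smoothing_window_ms))
  peak <- idx[arg_extreme(abs(seg - stats::median(seg)), maximum = TRUE)]
  half_qrs <- ms_to_sample(60, fs) - 1L
  qrs_rng <- max(1L, peak - half_qrs):min(n, peak + half_qrs)
  thr <- config$jpoint_deriv_frac * max(d[qrs_rng], na.rm = TRUE)
  hold <- ms_to_sample(config$jpoint_hold_ms, fs) - 1L
  below <- d < thr
  below[is.na(below)] <- FALSE
  i <- peak
  while (i - hold >= 1L) {
    if (all(below[(i - hold):i])) return(i)
    i <- i - 1L
  }
  stop("no QRS onset found within the trace")
}

#' Median J-point over all point maps
#'
#' The study-level J-point is the median of the per-point detections; for
#' an even count the lower of the two middle values is taken, so the result
#' is always one of the observed sample indices.
#'
#' @param jpoints integer vector of per-point J-point samples.
#' @return Median J-point sample index.
#' @export
median_jpoint <- function(jpoints) {
  jpoints <- jpoints[!is.na(jpoints)]
  if (length(jpoints) == 0L) stop("no J-points supplied")
  sort(jpoints)[ceiling(length(jpoints) / 2)]
}

#' Unipolar J-point elevation (Uni-JEl)
#'
#' Value of the unipolar electrogram at the study J-point minus its
#' baseline, the baseline being the median of a `baseline_window_ms`-long
#' segment ending at the QRS onset. When no onset is supplied the window is
#' anchored `qrs_pre_ms` before the J-point.
#'
#' @param trace unipolar electrogram (mV).
#' @param jpoint_sample study J-point (sample index).
#' @param fs sampling rate (Hz).
#' @param config an [feature_config()].
#' @param qrs_onset_sample optional QRS-onset sample (e.g. the median onset
#'   detected on the surface ECG).
#' @return J-point elevation in mV.
#' @export
compute_uni_jel <- function(trace, jpoint_sample, fs,
                            config = feature_config(),
                            qrs_onset_sample = NULL) {
  n <- length(trace)
  if (jpoint_sample < 1 || jpoint_sample > n)
    stop("jpoint_sample outside trace")
  if (is.null(qrs_onset_sample))
    qrs_onset_sample <- jpoint_sample - (ms_to_sample(config$qrs_pre_ms, fs) - 1L)
  b0 <- qrs_onset_sample - (ms_to_sample(config$baseline_window_ms, fs) - 1L)
  if (b0 < 1 || qrs_onset_sample > n)
    stop("baseline window outside trace")
  baseline <- stats::median(trace[b0:qrs_onset_sample])
  trace[jpoint_sample] - baseline
}

#' Local activation time (AT)
#'
#' Time of the steepest negative unipolar slope relative to the fiducial of
#' the V2 surface lead, both searched within the window of interest
#' `[reference_annotation + woi[1], reference_annotation + woi[2]]`. The V2
#' fiducial is its amplitude minimum by default (`v2_fiducial = "min"`), or
#' its steepest negative slope with `"dvdt_min"`. Ties break to the
#' earliest sample.
#'
#' @param unipolar unipolar electrogram (mV).
#' @param v2 surface-lead trace (mV).
#' @param reference_annotation timing reference (ms).
#' @param woi two-element window of interest (ms, relative).
#' @param fs sampling rate (Hz).
#' @param config an [feature_config()].
#' @return Activation time in ms (positive = later than the V2 fiducial).
#' @export
compute_at <- function(unipolar, v2, reference_annotation, woi, fs,
                       config = feature_config()) {
  w <- woi_samples(reference_annotation, woi, fs, length(unipolar))
  if (length(v2) < w[2]) stop("woi window outside the V2 trace")
  du <- smoothed_derivative(unipolar, fs, config$derivative_smoothing_window_ms)
  u_fid <- w[1] - 1L + arg_extreme(du[w[1]:w[2]])
  v_fid <- if (config$v2_fiducial == "min") {
    w[1] - 1L + arg_extreme(v2[w[1]:w[2]])
  } else {
    dv <- smoothed_derivative(v2, fs, config$derivative_smoothing_window_ms)
    w[1] - 1L + arg_extreme(dv[w[1]:w[2]])
  }
  (u_fid - v_fid) * 1000 / fs
}

woi_samples <- function(reference_annotation, woi, fs, n) {
  a <- ms_to_sample(reference_annotation + woi[1], fs)
  b <- ms_to_sample(reference_annotation + woi[2], fs)
  if (a < 1 || b > n) stop("woi window outside the trace")
  if (a >= b) stop("empty woi window")
  c(a, b)
}

#' Activation recovery interval (ARI, Wyatt method)
#'
#' Interval from the minimum dV/dt of the unipolar QRS (searched within the
#' window of interest) to the maximum dV/dt of the following T wave
#' (searched `t_search_min_ms`..`t_search_max_ms` after the depolarization
#' fiducial), the standard surrogate of local action-potential duration.
#' Each trace also receives a quality verdict ([assess_quality()]); traces
#' with noise, an extra beat in the window, or ambiguous T-wave morphology
#' should be discarded by the caller.
#'
#' @inheritParams compute_at
#' @return A list with `ari_ms` and `quality` (list with `accepted` and
#'   `reason`).
#' @export
compute_ari <- function(unipolar, reference_annotation, woi, fs,
                        config = feature_config()) {
  w <- woi_samples(reference_annotation, woi, fs, length(unipolar))
  du <- smoothed_derivative(unipolar, fs, config$derivative_smoothing_window_ms)
  dep <- w[1] - 1L + arg_extreme(du[w[1]:w[2]])
  r0 <- dep + ms_to_sample(config$t_search_min_ms, fs) - 1L
  r1 <- dep + ms_to_sample(config$t_search_max_ms, fs) - 1L
  if (r1 > length(unipolar)) stop("T-wave search window exceeds the trace")
  dt <- smoothed_derivative(unipolar, fs, config$t_smoothing_window_ms)
  rep_fid <- r0 - 1L + arg_extreme(dt[r0:r1], maximum = TRUE)
  quality <- assess_quality(unipolar,
                            list(dep_sample = dep, rep_sample = rep_fid,
                                 woi_samples = w, t_search = c(r0, r1)),
                            fs, config)
  list(ari_ms = (rep_fid - dep) * 1000 / fs, quality = quality)
}

#' Bazett-corrected ARI
#'
#' Heart-rate correction of the activation recovery interval:
#' `ARIc = ARI / sqrt(RR)` with RR expressed in seconds.
#'
#' @param ari_ms activation recovery interval (ms).
#' @param rr_ms RR interval (ms), must be positive.
#' @return Corrected interval in ms.
#' @export
compute_aric <- function(ari_ms, rr_ms) {
  if (any(rr_ms <= 0)) stop("rr_ms must be positive")
  ari_ms / sqrt(rr_ms / 1000)
}

#' Peak-to-peak unipolar voltage
#'
#' The per-point "unique unipolar value": the peak-to-peak amplitude
#' (max - min) of the unipolar electrogram within the window of interest.
#'
#' @inheritParams compute_at
#' @return Peak-to-peak amplitude in mV.
#' @export
compute_unipolar_voltage <- function(unipolar, reference_annotation, woi, fs) {
  w <- woi_samples(reference_annotation, woi, fs, length(unipolar))
  seg <- unipolar[w[1]:w[2]]
  max(seg) - min(seg)
}

#' Electrogram quality assessment
#'
#' Flags a unipolar trace for rejection when (in order of precedence):
#' * `noise` -- the RMS of the detrended pre-QRS baseline exceeds
#'   `noise_rms_max_mv`;
#' * `premature_beat` -- a second supra-threshold depolarization (smoothed
#'   derivative below half the main downstroke minimum, separated by more
#'   than 40 ms) occurs inside the window of interest;
#' * `abnormal_t_morphology` -- the two largest local maxima of the T-wave
#'   derivative are within 10% of each other (ambiguous repolarization
#'   fiducial), or the fiducial landed on a search-window boundary.
#'
#' @param trace unipolar electrogram (mV).
#' @param fiducials list with `dep_sample`, `rep_sample`, `woi_samples`
#'   (length-2) and `t_search` (length-2), as produced by [compute_ari()].
#' @param fs sampling rate (Hz).
#' @param config an [feature_config()].
#' @return List with `accepted` (logical) and `reason` (one of `"ok"`,
#'   `"noise"`, `"premature_beat"`, `"abnormal_t_morphology"`).
#' @export
assess_quality <- function(trace, fiducials, fs, config = feature_config()) {
  verdict <- function(reason) list(accepted = reason == "ok", reason = reason)
  w <- fiducials$woi_samples
  # baseline RMS before the window of interest
  nb <- ms_to_sample(config$baseline_window_ms, fs) - 1L
  b1 <- max(1L, w[1] - 1L)
  b0 <- max(1L, b1 - nb)
  base <- trace[b0:b1]
  if (sqrt(mean((base - stats::median(base))^2)) > config$noise_rms_max_mv)
    return(verdict("noise"))
  # second depolarization inside the woi
  du <- smoothed_derivative(trace, fs, config$derivative_smoothing_window_ms)
  seg <- du[w[1]:w[2]]
  main <- min(seg, na.rm = TRUE)
  hits <- which(seg <= 0.5 * main)
  if (length(hits) > 1L) {
    gaps <- diff(hits)
    if (any(gaps > ms_to_sample(40, fs) - 1L))
      return(verdict("premature_beat"))
  }
  # ambiguous T morphology
  r <- fiducials$t_search
  if (fiducials$rep_sample <= r[1] || fiducials$rep_sample >= r[2])
    return(verdict("abnormal_t_morphology"))
  dt <- smoothed_derivative(trace, fs, config$t_smoothing_window_ms)[r[1]:r[2]]
  locmax <- which(diff(sign(diff(dt))) == -2) + 1L
  if (length(locmax) >= 2L) {
    v <- sort(dt[locmax], decreasing = TRUE)
    min_dist_ms <- 30
    if (v[2] > 0 && (v[1] - v[2]) / abs(v[1]) < 0.10) {
      top2 <- locmax[order(dt[locmax], decreasing = TRUE)[1:2]]
      if (abs(diff(top2)) > ms_to_sample(min_dist_ms, fs) - 1L)
        return(verdict("abnormal_t_morphology"))
    }
  }
  verdict("ok")
}

#' Estimate the RR interval from a surface lead
#'
#' Median spacing of R peaks (local maxima above half the global maximum,
#' separated by a 300 ms refractory gap). Used for the Bazett correction
#' when no RR interval is supplied explicitly.
#'
#' @param trace ECG lead (mV).
#' @param fs sampling rate (Hz).
#' @return RR interval in ms, or `NA` if fewer than two beats are found.
#' @export
estimate_rr <- function(trace, fs) {
  thr <- 0.5 * max(trace)
  above <- trace > thr
  peaks <- integer(0)
  i <- 1L
  refract <- ms_to_sample(300, fs) - 1L
  while (i <= length(trace)) {
    if (above[i]) {
      j <- i
      while (j < length(trace) && above[j + 1L]) j <- j + 1L
      peaks <- c(peaks, i - 1L + which.max(trace[i:j]))
      i <- j + refract
    } else i <- i + 1L
  }
  if (length(peaks) < 2L) return(NA_real_)
  stats::median(diff(peaks)) * 1000 / fs
}

#' Extract all per-point features of a study
#'
#' Runs the full per-point pipeline: J-point detection on the configured
#' ECG lead, median J-point and QRS onset, then Uni-JEl, AT, ARI (with
#' quality verdict), Bazett-corrected ARI and peak-to-peak unipolar voltage
#' for every electro-anatomical point.
#'
#' @param study an [epm_study()] with the configured ECG lead present.
#' @param config an [feature_config()].
#' @param rr_ms RR interval for the Bazett correction; estimated from the
#'   ECG lead when `NULL`.
#' @return A data.frame with one row per point: `point_id`, surface
#'   coordinates `x`,`y`,`z`, `uni_jel_mv`, `at_ms`, `ari_ms`, `aric_ms`,
#'   `uni_pp_mv`, `quality` (logical) and `reason`. The study J-point and
#'   RR are attached as attributes `jpoint_sample` and `rr_ms`.
#' @export
extract_features <- function(study, config = feature_config(), rr_ms = NULL) {
  lead <- config$lead_for_jpoint
  if (!lead %in% names(study$ecg))
    stop("study has no ECG lead ", lead)
  v2 <- study$ecg[[lead]]
  fs <- study$sampling_rate
  ref <- study$reference_annotation
  search <- c(ms_to_sample(ref + study$woi[1], fs),
              min(length(v2), ms_to_sample(ref + study$woi[2] + 100, fs)))
  jp <- median_jpoint(detect_jpoint(v2, fs, config, search = search))
  onset <- detect_qrs_onset(v2, fs, config, search = search)
  if (is.null(rr_ms)) {
    rr_ms <- estimate_rr(v2, fs)
    if (is.na(rr_ms)) {
      rr_ms <- 1000
      message("RR interval not estimable from the ECG; using 1000 ms")
    }
  }
  p <- n_points(study)
  out <- data.frame(point_id = seq_len(p),
                    x = study$surface_positions[, 1],
                    y = study$surface_positions[, 2],
                    z = study$surface_positions[, 3],
                    uni_jel_mv = NA_real_, at_ms = NA_real_,
                    ari_ms = NA_real_, aric_ms = NA_real_,
                    uni_pp_mv = NA_real_, quality = NA, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(p)) {
    u <- study$unipolar[i, ]
    out$uni_jel_mv[i] <- compute_uni_jel(u, jp, fs, config,
                                         qrs_onset_sample = onset)
    out$at_ms[i] <- compute_at(u, v2, ref, study$woi, fs, config)
    ari <- compute_ari(u, ref, study$woi, fs, config)
    out$ari_ms[i] <- ari$ari_ms
    out$aric_ms[i] <- compute_aric(ari$ari_ms, rr_ms)
    out$uni_pp_mv[i] <- compute_unipolar_voltage(u, ref, study$woi, fs)
    out$quality[i] <- ari$quality$accepted
    out$reason[i] <- ari$quality$reason
  }
  attr(out, "jpoint_sample") <- jp
  attr(out, "rr_ms") <- rr_ms
  out
}
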