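#' Filter points by catheter contact force
#'
#' Acquisition-quality gate: points acquired with poor tissue contact give
#' unreliable electrograms, so points with a contact force outside
#' `[min_g, max_g]` grams are discarded (bounds inclusive: the clinical
#' rule discards strictly below 5 g or strictly above 25 g). Points whose
#' force was not recorded are retained but flagged `"force_unknown"`. The
#' input study is not modified; the operation is idempotent and preserves
#' point order.
#'
#' @param study an [epm_study()].
#' @param min_g,max_g inclusive force bounds in grams (defaults 5 and 25).
#' @return A new [epm_study()] with the out-of-range points removed.
#' @export
filter_points_by_force <- function(study, min_g = 5, max_g = 25) {
  if (min_g > max_g) stop("min_g must be <= max_g")
  force <- study$contact_force
  unknown <- is.na(force)
  keep <- unknown | (force >= min_g & force <= max_g)
  if (!any(keep)) warning("no points satisfy the contact-force bounds")
  out <- subset_points(study, keep)
  flag <- unknown[keep] & out$reason == ""
  out$reason[flag] <- "force_unknown"
  out
}

#' Zero-phase band-pass filtering of electrogram traces
#'
#' Optional preprocessing replicating the acquisition-side analog bands
#' (unipolar 1--240 Hz, bipolar 30--500 Hz). Implemented as a zero-phase
#' FFT brick-wall filter so fiducial timings are not shifted; off by
#' default in every pipeline because clinical exports are already
#' band-limited by the recording system.
#'
#' @param study an [epm_study()].
#' @param low_hz,high_hz pass-band edges (Hz); `high_hz` is capped at the
#'   Nyquist frequency.
#' @param channel `"unipolar"` (default) or `"bipolar"`.
#' @return A new [epm_study()] with the filtered traces.
#' @export
bandpass_traces <- function(study, low_hz = 1, high_hz = 240,
                            channel = c("unipolar", "bipolar")) {
  channel <- match.arg(channel)
  x <- study[[channel]]
  if (is.null(x)) stop("study has no ", channel, " traces")
  if (nrow(x) == 0L) return(study)
  n <- ncol(x)
  freqs <- (seq_len(n) - 1) * study$sampling_rate / n
  freqs <- pmin(freqs, study$sampling_rate - freqs)   # two-sided
  keep <- freqs >= low_hz & freqs <= min(high_hz, study$sampling_rate / 2)
  keep[1] <- low_hz <= 0                               # DC
  out <- study
  ft <- t(apply(x, 1, function(row) {
    X <- stats::fft(row)
    X[!keep] <- 0
    Re(stats::fft(X, inverse = TRUE)) / n
  }))
  out[[channel]] <- ft
  out
}
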