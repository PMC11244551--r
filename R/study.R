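#' Electro-anatomical mapping study container
#'
#' One acquisition phase of an HDEAM study: the reconstructed chamber
#' surface, the sampled electro-anatomical points (catheter position,
#' surface projection, electrogram traces, contact force), the surface ECG,
#' and the timing metadata used for fiducial search (reference annotation
#' and window of interest).
#'
#' Point data are stored columnar: `positions` and `surface_positions` are
#' P x 3 matrices, `unipolar` (and optional `bipolar`) are P x T trace
#' matrices in mV, `contact_force` is a length-P vector in grams (`NA` when
#' the catheter reported none), and `valid`/`reason` carry per-point
#' acquisition-quality flags.
#'
#' @param mesh an [epm_mesh()].
#' @param positions P x 3 matrix of acquisition coordinates (mm).
#' @param surface_positions P x 3 matrix of the same points projected onto
#'   the surface (mm); computed with [project_to_surface()] when `NULL`.
#' @param unipolar P x T matrix of unipolar electrograms (mV).
#' @param bipolar optional P x T matrix of bipolar electrograms (mV).
#' @param contact_force numeric length-P vector (grams), `NA` allowed.
#' @param valid logical length-P vector; defaults to all `TRUE`.
#' @param reason character length-P rejection reasons ("" when valid).
#' @param ecg named list of numeric traces (mV), one per surface lead,
#'   names drawn from I, II, III, aVR, aVL, aVF, V1..V6; shared by all
#'   points of the study.
#' @param sampling_rate sampling rate in Hz for all traces.
#' @param reference_annotation timing reference in ms from trace start.
#' @param woi two-element window of interest in ms relative to
#'   `reference_annotation` (default `c(-100, 100)`).
#' @param phase_label free-text phase tag, e.g. `"pre"` or `"post"`.
#' @return An object of class `epm_study`.
#' @export
epm_study <- function(mesh, positions, unipolar,
                      surface_positions = NULL,
                      bipolar = NULL,
                      contact_force = NULL,
                      valid = NULL,
                      reason = NULL,
                      ecg = list(),
                      sampling_rate = 1000,
                      reference_annotation = 2000,
                      woi = c(-100, 100),
                      phase_label = "") {
  stopifnot(inherits(mesh, "epm_mesh"))
  positions <- as_xyz(positions)
  p <- nrow(positions)
  unipolar <- as_traces(unipolar, p)
  if (!is.null(bipolar)) {
    bipolar <- as_traces(bipolar, p)
    if (ncol(bipolar) != ncol(unipolar))
      stop("bipolar traces must match unipolar trace length")
  }
  if (is.null(surface_positions)) {
    surface_positions <- if (p > 0) project_to_surface(positions, mesh)
                         else positions
    attributes(surface_positions) <- attributes(surface_positions)["dim"]
  } else {
    surface_positions <- as_xyz(surface_positions)
    if (nrow(surface_positions) != p)
      stop("surface_positions must match positions")
  }
  if (is.null(contact_force)) contact_force <- rep(NA_real_, p)
  contact_force <- as.numeric(contact_force)
  contact_force[is.nan(contact_force)] <- NA_real_
  if (length(contact_force) != p) stop("contact_force must have one entry per point")
  if (any(contact_force < 0, na.rm = TRUE)) stop("contact_force must be >= 0")
  if (is.null(valid)) valid <- rep(TRUE, p)
  if (is.null(reason)) reason <- ifelse(valid, "", "invalid")
  stopifnot(length(valid) == p, length(reason) == p)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  woi <- as.numeric(woi)
  if (length(woi) != 2L || !(woi[1] < woi[2])) stop("woi must satisfy woi[1] < woi[2]")
  validate_ecg(ecg)
  # canonical lead order so containers round-trip identically
  if (length(ecg) > 0) ecg <- ecg[order(match(names(ecg), STANDARD_LEADS))]
  tmax_ms <- (ncol(unipolar) - 1) * 1000 / sampling_rate
  if (p > 0 && (reference_annotation + woi[1] < 0 ||
                reference_annotation + woi[2] > tmax_ms))
    stop("reference_annotation + woi must fall inside the trace extent")
  structure(list(mesh = mesh,
                 positions = positions,
                 surface_positions = surface_positions,
                 unipolar = unipolar,
                 bipolar = bipolar,
                 contact_force = contact_force,
                 valid = as.logical(valid),
                 reason = as.character(reason),
                 ecg = ecg,
                 sampling_rate = as.numeric(sampling_rate),
                 reference_annotation = as.numeric(reference_annotation),
                 woi = woi,
                 phase_label = as.character(phase_label)),
            class = "epm_study")
}

as_xyz <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0L) x <- matrix(numeric(0), 0L, 3L)
  if (ncol(x) != 3L) stop("coordinate matrices must have 3 columns")
  storage.mode(x) <- "double"
  x
}

as_traces <- function(x, p) {
  x <- as.matrix(x)
  if (length(x) == 0L && p == 0L) x <- matrix(numeric(0), 0L, max(1L, ncol(x)))
  if (nrow(x) != p) stop("trace matrix must have one row per point")
  storage.mode(x) <- "double"
  x
}

STANDARD_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                    "V1", "V2", "V3", "V4", "V5", "V6")

validate_ecg <- function(ecg) {
  if (length(ecg) == 0L) return(invisible(TRUE))
  if (is.null(names(ecg)) || any(!names(ecg) %in% STANDARD_LEADS))
    stop("ecg lead names must be among: ", paste(STANDARD_LEADS, collapse = ", "))
  n <- unique(vapply(ecg, length, 1L))
  if (length(n) != 1L) stop("all ecg leads must have the same length")
  invisible(TRUE)
}

#' Number of electro-anatomical points in a study
#' @param study an [epm_study()].
#' @return Integer point count.
#' @export
n_points <- function(study) nrow(study$positions)

#' @export
print.epm_study <- function(x, ...) {
  cat(sprintf(paste0("<epm_study> phase '%s': %d points, %d-vertex mesh, ",
                     "fs %g Hz, ref %g ms, woi [%g, %g] ms\n"),
              x$phase_label, n_points(x), nrow(x$mesh$vertices),
              x$sampling_rate, x$reference_annotation, x$woi[1], x$woi[2]))
  invisible(x)
}

# Subset a study's point-parallel arrays, preserving order.
subset_points <- function(study, keep) {
  s <- study
  s$positions <- study$positions[keep, , drop = FALSE]
  s$surface_positions <- study$surface_positions[keep, , drop = FALSE]
  s$unipolar <- study$unipolar[keep, , drop = FALSE]
  if (!is.null(study$bipolar)) s$bipolar <- study$bipolar[keep, , drop = FALSE]
  s$contact_force <- study$contact_force[keep]
  s$valid <- study$valid[keep]
  s$reason <- study$reason[keep]
  s
}
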