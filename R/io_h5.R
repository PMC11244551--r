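#' Save a study to the native HDF5 container
#'
#' Fixed-layout HDF5 file (all units mm / ms / mV / grams, indices
#' 0-based, trace matrices point-major):
#' \preformatted{
#' /mesh/vertices          N x 3 float64 (mm)
#' /mesh/triangles         M x 3 int32, 0-based
#' /points/position        P x 3 float64 (mm)
#' /points/surface_position P x 3 float64 (mm)
#' /points/contact_force   P float64 (grams, NaN = missing)
#' /points/valid           P int32 (0/1)
#' /points/reason          P string
#' /signals/unipolar       P x T float64 (mV)
#' /signals/bipolar        P x T float64 (optional)
#' /ecg/<lead>             T float64 (mV)
#' root attributes: sampling_rate_hz, reference_annotation_ms,
#'   woi_ms (2-vector), phase_label, format_version, index_base, units
#' }
#' Dataset shapes above are as seen by C-order readers (h5py, h5dump);
#' `load_study(save_study(x))` reproduces every array bit-identically.
#'
#' @param study an [epm_study()].
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
save_study <- function(study, path) {
  stopifnot(inherits(study, "epm_study"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (g in c("mesh", "points", "signals", "ecg"))
    rhdf5::h5createGroup(path, g)
  # R matrices are column-major: writing t(m) makes C-order readers see
  # the natural row-per-record shape.
  w <- function(obj, name) rhdf5::h5write(obj, path, name)
  w(t(study$mesh$vertices), "mesh/vertices")
  w(t(study$mesh$triangles - 1L), "mesh/triangles")
  w(t(study$positions), "points/position")
  w(t(study$surface_positions), "points/surface_position")
  force <- study$contact_force
  force[is.na(force)] <- NaN
  w(force, "points/contact_force")
  w(as.integer(study$valid), "points/valid")
  w(study$reason, "points/reason")
  w(t(study$unipolar), "signals/unipolar")
  if (!is.null(study$bipolar)) w(t(study$bipolar), "signals/bipolar")
  for (lead in names(study$ecg)) w(study$ecg[[lead]], paste0("ecg/", lead))
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(study$sampling_rate, fid, "sampling_rate_hz")
  rhdf5::h5writeAttribute(study$reference_annotation, fid,
                          "reference_annotation_ms")
  rhdf5::h5writeAttribute(study$woi, fid, "woi_ms")
  rhdf5::h5writeAttribute(study$phase_label, fid, "phase_label")
  rhdf5::h5writeAttribute("1.0", fid, "format_version")
  rhdf5::h5writeAttribute(0L, fid, "index_base")
  rhdf5::h5writeAttribute("mm/ms/mV/grams", fid, "units")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load a study from the native HDF5 container
#'
#' @param path file written by [save_study()].
#' @return An [epm_study()].
#' @export
load_study <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  present <- paste(ls$group, ls$name, sep = "/")
  present <- sub("^//", "/", present)
  required <- c("/mesh/vertices", "/mesh/triangles", "/points/position",
                "/points/surface_position", "/signals/unipolar")
  miss <- setdiff(required, present)
  if (length(miss) > 0)
    stop("not a valid study container: missing ", paste(miss, collapse = ", "))
  att <- rhdf5::h5readAttributes(path, "/")
  if (is.null(att$format_version))
    stop("not a valid study container: missing format_version attribute")
  if (!identical(as.character(att$format_version), "1.0"))
    stop("unsupported container version: ", att$format_version)
  r <- function(name) rhdf5::h5read(path, name)
  tr <- function(name) t(r(name))
  vertices <- tr("mesh/vertices")
  triangles <- tr("mesh/triangles") + 1L
  mesh <- epm_mesh(vertices, triangles)
  force <- as.numeric(r("points/contact_force"))
  force[is.nan(force)] <- NA_real_
  ecg <- list()
  for (lead in ls$name[ls$group == "/ecg"])
    ecg[[lead]] <- as.numeric(r(paste0("ecg/", lead)))
  ecg <- ecg[order(match(names(ecg), STANDARD_LEADS))]
  epm_study(mesh,
            positions = tr("points/position"),
            surface_positions = tr("points/surface_position"),
            unipolar = tr("signals/unipolar"),
            bipolar = if ("/signals/bipolar" %in% present)
              tr("signals/bipolar") else NULL,
            contact_force = force,
            valid = as.logical(r("points/valid")),
            reason = as.character(r("points/reason")),
            ecg = ecg,
            sampling_rate = as.numeric(att$sampling_rate_hz),
            reference_annotation = as.numeric(att$reference_annotation_ms),
            woi = as.numeric(att$woi_ms),
            phase_label = as.character(att$phase_label))
}
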