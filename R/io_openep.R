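#' Import an OpenEP-style userdata MAT file
#'
#' Reads the MATLAB `userdata` structure that electro-anatomical mapping
#' exports are converted into: electrode positions (`egmX`), their surface
#' projections (`egmSurfX`), unipolar electrograms (`egm`), the surface
#' ECG, the reference annotation and window of interest, and the
#' triangulated chamber surface. Only MAT v7.3 containers (which are HDF5
#' underneath) are supported; older v5/v7 MAT files have no parser in this
#' environment and raise an error. Unknown extra fields are ignored with a
#' message. Points whose electrogram is entirely non-finite are flagged
#' invalid rather than dropped; a missing `egmSurfX` is reconstructed by
#' nearest-point projection onto the surface (with a warning).
#'
#' @param path MAT v7.3 file.
#' @param sampling_rate fallback sampling rate (Hz) when the file carries
#'   none.
#' @return An [epm_study()].
#' @export
import_openep <- function(path, sampling_rate = 1000) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!is_hdf5_file(path))
    stop("only MAT v7.3 (HDF5-based) files are supported; ",
         "re-save the userdata with '-v7.3' in MATLAB")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  ls$full <- sub("^//", "/", paste(ls$group, ls$name, sep = "/"))
  # locate fields regardless of nesting (userdata/electric/egmX vs /egmX)
  find1 <- function(name) {
    hit <- ls$full[grepl(paste0("(^|/)", name, "$"), ls$full) &
                     ls$otype == "H5I_DATASET"]
    if (length(hit) == 0) NULL else hit[1]
  }
  known <- c("egmX", "egmSurfX", "egm", "ecg", "referenceAnnotation", "woi",
             "X", "Triangulation", "sampleFrequency")
  loc <- lapply(known, find1)
  names(loc) <- known
  required <- c("egmX", "egm", "X", "Triangulation")
  miss <- required[vapply(loc[required], is.null, TRUE)]
  if (length(miss) > 0)
    stop("userdata import failed; missing field(s): ",
         paste(miss, collapse = ", "))
  extra <- ls$full[ls$otype == "H5I_DATASET" &
                     !ls$full %in% unlist(loc) &
                     !grepl("#refs#", ls$full)]
  if (length(extra) > 0)
    message("ignoring ", length(extra), " unrecognised field(s): ",
            paste(utils::head(basename(extra), 5), collapse = ", "),
            if (length(extra) > 5) ", ..." else "")

  # MATLAB v7.3 stores arrays transposed w.r.t. C order; rhdf5's
  # column-major read undoes that, so matrices come back in MATLAB shape.
  rd <- function(name) {
    x <- rhdf5::h5read(path, loc[[name]])
    if (is.array(x) && length(dim(x)) == 2 && any(dim(x) == 1) &&
        length(x) > 0) x <- as.numeric(x)
    x
  }
  vertices <- as_mat(rd("X"), 3)
  triangles <- as_mat(rd("Triangulation"), 3)   # MATLAB 1-based
  mesh <- epm_mesh(vertices, round(triangles))

  pos <- as_mat(rd("egmX"), 3)
  egm <- as.matrix(rd("egm"))
  if (nrow(egm) != nrow(pos) && ncol(egm) == nrow(pos)) egm <- t(egm)

  if (!is.null(loc$egmSurfX)) {
    surf <- as_mat(rd("egmSurfX"), 3)
  } else {
    warning("egmSurfX absent; computing surface projections from egmX")
    surf <- project_to_surface(pos, mesh)
    attributes(surf) <- attributes(surf)["dim"]
  }

  ref <- if (!is.null(loc$referenceAnnotation)) {
    v <- as.numeric(rd("referenceAnnotation"))
    if (length(unique(v)) > 1)
      warning("per-point referenceAnnotation varies; using the median")
    stats::median(v)
  } else {
    warning("referenceAnnotation absent; defaulting to 2000 ms")
    2000
  }
  woi <- if (!is.null(loc$woi)) {
    w <- rd("woi")
    if (is.matrix(w)) w <- w[1, ]
    as.numeric(w)[1:2]
  } else {
    warning("woi absent; defaulting to [-100, 100] ms")
    c(-100, 100)
  }
  fs <- if (!is.null(loc$sampleFrequency)) as.numeric(rd("sampleFrequency"))[1]
        else {
          warning("no sampling rate in file; assuming ", sampling_rate, " Hz")
          sampling_rate
        }

  ecg <- list()
  if (!is.null(loc$ecg)) {
    e <- rd("ecg")
    if (is.matrix(e) && nrow(e) > 12 && ncol(e) <= 12) e <- t(e)
    if (is.matrix(e) && nrow(e) <= 12) {
      # rows = leads in standard order
      for (i in seq_len(nrow(e))) ecg[[STANDARD_LEADS[i]]] <- e[i, ]
    } else if (!is.matrix(e)) {
      ecg[["V2"]] <- as.numeric(e)
    }
  }

  bad <- apply(egm, 1, function(x) all(!is.finite(x)))
  egm[!is.finite(egm)] <- 0
  epm_study(mesh, positions = pos, surface_positions = surf,
            unipolar = egm, ecg = ecg, sampling_rate = fs,
            reference_annotation = ref, woi = woi,
            valid = !bad, reason = ifelse(bad, "no_trace", ""),
            phase_label = "imported")
}

as_mat <- function(x, k) {
  x <- as.matrix(x)
  if (ncol(x) != k && nrow(x) == k) x <- t(x)
  storage.mode(x) <- "double"
  x
}

# HDF5 superblock at offset 0 or 512 (MAT v7.3 prefixes a 512-byte header).
is_hdf5_file <- function(path) {
  sig <- as.raw(c(0x89, 0x48, 0x44, 0x46, 0x0d, 0x0a, 0x1a, 0x0a))
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 8)
  if (identical(head, sig)) return(TRUE)
  seek(con, 512)
  identical(readBin(con, "raw", 8), sig)
}

# Write a synthetic OpenEP-style userdata MAT v7.3 file (HDF5 payload with
# MATLAB-convention array orientation plus the 512-byte MAT header). Used
# by the test-suite fixtures and the simulate CLI; not a full MAT writer.
write_openep_mat <- function(study, path) {
  tmp <- tempfile(fileext = ".h5")
  rhdf5::h5createFile(tmp)
  on.exit({rhdf5::h5closeAll(); unlink(tmp)}, add = TRUE)
  rhdf5::h5createGroup(tmp, "userdata")
  rhdf5::h5createGroup(tmp, "userdata/electric")
  rhdf5::h5createGroup(tmp, "userdata/electric/annotations")
  rhdf5::h5createGroup(tmp, "userdata/surface")
  rhdf5::h5createGroup(tmp, "userdata/surface/triRep")
  # R write of an n x k matrix appears as (k, n) to C-order readers, which
  # is exactly how MATLAB v7.3 lays out an n x k array.
  w <- function(obj, name) rhdf5::h5write(obj, tmp, name)
  w(study$positions, "userdata/electric/egmX")
  w(study$surface_positions, "userdata/electric/egmSurfX")
  w(study$unipolar, "userdata/electric/egm")
  if (length(study$ecg) > 0) {
    leads <- match(names(study$ecg), STANDARD_LEADS)
    e <- matrix(0, max(leads), length(study$ecg[[1]]))
    for (i in seq_along(study$ecg)) e[leads[i], ] <- study$ecg[[i]]
    w(e, "userdata/electric/ecg")
  }
  w(rep(study$reference_annotation, n_points(study)),
    "userdata/electric/annotations/referenceAnnotation")
  w(matrix(study$woi, n_points(study), 2, byrow = TRUE),
    "userdata/electric/annotations/woi")
  w(study$sampling_rate, "userdata/electric/sampleFrequency")
  w(study$mesh$vertices, "userdata/surface/triRep/X")
  w(matrix(as.numeric(study$mesh$triangles), nrow(study$mesh$triangles)),
    "userdata/surface/triRep/Triangulation")
  rhdf5::h5closeAll()
  hdr <- raw(512)
  txt <- charToRaw("MATLAB 7.3 MAT-file, created by epmap")
  hdr[seq_along(txt)] <- txt
  hdr[125:126] <- as.raw(c(0x00, 0x02))
  hdr[127:128] <- charToRaw("IM")
  payload <- readBin(tmp, "raw", file.size(tmp))
  con <- file(path, "wb")
  writeBin(c(hdr, payload), con)
  close(con)
  invisible(path)
}
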