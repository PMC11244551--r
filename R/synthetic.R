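#' Synthetic right-ventricle surface mesh
#'
#' Builds a closed, watertight chamber surface for simulation: an
#' icosphere deformed into an ellipsoid (semi-axes 30 x 25 x 45 mm,
#' roughly right-ventricular dimensions) with a localized outward bulge
#' standing in for the right ventricular outflow tract (RVOT), plus a
#' small seeded smooth irregularity so no two seeds give the same
#' geometry. The vertex IDs of the bulge patch are returned in the
#' `"rvot_vertices"` attribute so tests and examples can target it as a
#' region of interest.
#'
#' @param n_subdivisions icosphere subdivision level (0 = icosahedron,
#'   20 triangles; each level quadruples the triangle count).
#' @param bulge_amplitude outward displacement of the RVOT-analog patch
#'   in mm (0 disables it).
#' @param seed integer seed controlling the smooth surface irregularity;
#'   the same seed always yields the same mesh.
#' @return An [epm_mesh()] with attributes `rvot_vertices` (integer IDs)
#'   and `seed`.
#' @export
make_rv_mesh <- function(n_subdivisions = 3, bulge_amplitude = 6, seed = 1) {
  if (n_subdivisions < 0) stop("n_subdivisions must be >= 0")
  ico <- icosphere(n_subdivisions)
  v <- ico$vertices   # unit sphere
  set.seed(seed)
  # smooth low-order radial irregularity (~2% of radius)
  r <- rep(1, nrow(v))
  for (k in 1:3) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    ph <- runif(1, 0, 2 * pi)
    r <- r + 0.02 * sin(3 * as.numeric(v %*% d) + ph)
  }
  axes <- c(30, 25, 45)
  xyz <- v * r
  xyz <- sweep(xyz, 2, axes, "*")
  # RVOT-analog bulge: outward radial displacement within an angular cap
  u0 <- c(0.55, 0.35, 0.76); u0 <- u0 / sqrt(sum(u0^2))
  ct <- pmin(1, pmax(-1, as.numeric(v %*% u0)))
  theta <- acos(ct)
  theta0 <- 0.55
  cap <- theta < theta0
  if (bulge_amplitude != 0) {
    w <- cos(pi * theta[cap] / (2 * theta0))^2
    xyz[cap, ] <- xyz[cap, ] + bulge_amplitude * w * v[cap, , drop = FALSE]
  }
  m <- epm_mesh(xyz, ico$triangles)
  attr(m, "rvot_vertices") <- which(cap)
  attr(m, "seed") <- seed
  m
}

# Unit icosphere: icosahedron plus midpoint subdivision.
icosphere <- function(n_subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(n_subdivisions)) {
    midpoint <- new.env(parent = emptyenv())
    nv <- nrow(v)
    extra <- list()
    get_mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- midpoint[[key]]
      if (is.null(idx)) {
        m <- (v[a, ] + v[b, ]) / 2
        m <- m / sqrt(sum(m^2))
        extra[[length(extra) + 1L]] <<- m
        idx <- nv + length(extra)
        midpoint[[key]] <- idx
      }
      idx
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c3 <- f[i, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, c3); ca <- get_mid(c3, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, extra))
    f <- nf
  }
  list(vertices = v, triangles = f)
}

#' Sample points uniformly on a mesh surface
#'
#' Area-weighted triangle selection followed by uniform barycentric
#' placement, giving unbiased coverage of the surface.
#'
#' @param mesh an [epm_mesh()].
#' @param n number of points.
#' @return n x 3 matrix of surface coordinates.
#' @export
sample_surface_points <- function(mesh, n) {
  ar <- triangle_areas(mesh)
  ti <- sample.int(nrow(mesh$triangles), n, replace = TRUE, prob = ar)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  a <- 1 - r1; b <- r1 * (1 - r2); c3 <- r1 * r2
  tri <- mesh$triangles[ti, , drop = FALSE]
  mesh$vertices[tri[, 1], , drop = FALSE] * a +
    mesh$vertices[tri[, 2], , drop = FALSE] * b +
    mesh$vertices[tri[, 3], , drop = FALSE] * c3
}

# ---------------------------------------------------------------------------
# Electrogram template.
#
# The unipolar trace is a sum of analytically placed components (times in
# ms, t_dep = ref + at_offset, t_rep = t_dep + ari):
#   depolarization downstroke: -rs_amp * plogis((t - t_dep)/2.5)
#     -> steepest NEGATIVE slope exactly at t_dep (logistic density is
#        symmetric, so symmetric derivative smoothing cannot shift it)
#   fast recovery:              rs_amp * plogis((t - t_dep - 14)/4)
#     (returns the trace near baseline well before the study J-point)
#   T wave: t_amp * plogis((t - t_rep)/8) * falloff(t), where falloff is 1
#     until t_rep + 60 and decays to 0 as cos^2 over the next 120 ms
#     -> steepest POSITIVE slope exactly at t_rep, and the compact decay
#        keeps the pre-QRS baseline free of T-wave tails
#   ST component: k * ramp(t), a smoothstep that is identically zero
#     before t_dep + 8, rises to 1 at the study J-point, holds for 10 ms
#     and decays to zero over 55 ms; k is solved so the trace value at the
#     J-point equals jel exactly. The rising edge has positive slope (it
#     cannot disturb the downstroke argmin) and the falling-edge slope
#     k*pi/110 stays well below the downstroke slope rs_amp/10 for the
#     amplitudes the generator allows; compact support keeps the pre-QRS
#     baseline identically zero.
# Validity domain: the J-point must come >= 12 ms after t_dep; the
# generator enforces this.
# ---------------------------------------------------------------------------
EGM_W_DEP <- 2.5; EGM_REC_DELAY <- 14; EGM_W_REC <- 4
EGM_W_TUP <- 8; EGM_T_HOLD <- 60; EGM_T_FALL <- 120
EGM_ST_START <- 8; EGM_ST_HOLD <- 10; EGM_ST_FALL <- 55
EGM_MIN_J_GAP <- 12

# Noise-free component bank evaluated for P points at once; tt in ms.
egm_bank_clean <- function(tt, t_dep, ari, jel, t_j_ms, rs_amp, t_amp) {
  if (any(t_j_ms - t_dep < EGM_MIN_J_GAP))
    stop("activation too close to the study J-point for the template ",
         "(need t_j - t_dep >= ", EGM_MIN_J_GAP, " ms)")
  u <- -rs_amp * plogis(outer(-t_dep, tt, "+") / EGM_W_DEP)
  u <- u + rs_amp * plogis(outer(-(t_dep + EGM_REC_DELAY), tt, "+") / EGM_W_REC)
  t_rep <- t_dep + ari
  xr <- outer(-t_rep, tt, "+")            # time since repolarization fiducial
  falloff <- matrix(1, nrow(xr), ncol(xr))
  falloff[xr >= EGM_T_HOLD + EGM_T_FALL] <- 0
  mid <- xr > EGM_T_HOLD & xr < EGM_T_HOLD + EGM_T_FALL
  falloff[mid] <- cos(pi * (xr[mid] - EGM_T_HOLD) / (2 * EGM_T_FALL))^2
  u <- u + t_amp * plogis(xr / EGM_W_TUP) * falloff
  # solve ST amplitude so U(t_j) == jel exactly
  base_at_j <- u[, which.min(abs(tt - t_j_ms))]
  k <- jel - base_at_j
  # per-point smoothstep ramp: 0 before t_dep+8, 1 at t_j, decay after
  x <- outer(-t_dep, tt, "+")            # time since depolarization
  rise_end <- t_j_ms - t_dep             # per-point rise length (vector)
  ramp <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    L <- rise_end[i] - EGM_ST_START
    r <- numeric(length(xi))
    rising <- xi > EGM_ST_START & xi < rise_end[i]
    r[rising] <- sin(pi * (xi[rising] - EGM_ST_START) / (2 * L))^2
    r[xi >= rise_end[i] & xi <= rise_end[i] + EGM_ST_HOLD] <- 1
    falling <- xi > rise_end[i] + EGM_ST_HOLD &
      xi < rise_end[i] + EGM_ST_HOLD + EGM_ST_FALL
    r[falling] <- cos(pi * (xi[falling] - rise_end[i] - EGM_ST_HOLD) /
                        (2 * EGM_ST_FALL))^2
    ramp[i, ] <- r
  }
  u + ramp * k
}

#' Synthetic unipolar electrogram with known fiducials
#'
#' Builds a single unipolar trace whose depolarization fiducial (steepest
#' negative slope), repolarization fiducial (steepest positive T-wave
#' slope) and J-point elevation are placed analytically, so feature
#' extractors can be validated against exact ground truth. See the
#' package vignette for the waveform model.
#'
#' @param fs sampling rate (Hz).
#' @param ref_ms timing reference (ms from trace start).
#' @param at_offset_ms activation offset: the steepest downstroke occurs at
#'   `ref_ms + at_offset_ms`.
#' @param ari_ms activation recovery interval: the steepest T-wave upstroke
#'   occurs `ari_ms` after the downstroke.
#' @param rs_amp_mv QRS deflection amplitude (mV).
#' @param t_amp_mv T-wave amplitude (mV).
#' @param jel_mv J-point elevation above baseline (mV), exact before noise.
#' @param noise_sd_mv white-noise standard deviation (mV).
#' @param seed optional integer seed for the noise.
#' @param duration_ms trace duration (default `ref_ms + 700`).
#' @param jpoint_offset_ms J-point position relative to `ref_ms` (ms); in a
#'   full synthetic study this is set to the J-point detected on the
#'   study's V2 lead.
#' @return Numeric trace (mV) with attribute `fiducials`, a list with
#'   `t_dep_ms`, `t_rep_ms`, `t_j_ms` and `jel_mv`.
#' @export
make_unipolar_egm <- function(fs = 1000, ref_ms = 2000, at_offset_ms = 20,
                              ari_ms = 250, rs_amp_mv = 2, t_amp_mv = 1,
                              jel_mv = 0, noise_sd_mv = 0, seed = NULL,
                              duration_ms = ref_ms + 700,
                              jpoint_offset_ms = 65) {
  if (fs <= 0) stop("fs must be > 0")
  if (ari_ms <= 0) stop("ari_ms must be > 0")
  n <- round(duration_ms * fs / 1000) + 1
  tt <- (seq_len(n) - 1) * 1000 / fs
  t_dep <- ref_ms + at_offset_ms
  t_rep <- t_dep + ari_ms
  if (t_dep - 20 < 0 || t_rep + EGM_T_HOLD + EGM_T_FALL > duration_ms)
    stop("fiducials fall outside the trace; increase duration_ms")
  u <- egm_bank_clean(tt, t_dep, ari_ms, jel_mv,
                      ref_ms + jpoint_offset_ms, rs_amp_mv, t_amp_mv)[1, ]
  if (noise_sd_mv > 0) {
    if (!is.null(seed)) set.seed(seed)
    u <- u + rnorm(n, 0, noise_sd_mv)
  }
  attr(u, "fiducials") <- list(t_dep_ms = t_dep, t_rep_ms = t_rep,
                               t_j_ms = ref_ms + jpoint_offset_ms,
                               jel_mv = jel_mv)
  u
}

# Synthetic V2 surface lead: R wave, deep S wave with its minimum exactly
# at the reference annotation, a small terminal-delay wave that pushes the
# detected QRS offset (J-point) to ~ref+65 ms, and an ST/T complex. One
# slightly smaller preceding beat is added so the RR interval (1000 ms)
# can be estimated from the trace while the global minimum stays at the
# reference annotation.
make_v2_trace <- function(fs, ref_ms, n_samples, rr_ms = 1000) {
  tt <- (seq_len(n_samples) - 1) * 1000 / fs
  beat <- function(centre, scale = 1) {
    scale * (1.2 * exp(-(tt - (centre - 30))^2 / (2 * 7^2)) -
               1.5 * exp(-(tt - centre)^2 / (2 * 9^2)) +
               0.3 * exp(-(tt - (centre + 35))^2 / (2 * 8^2)) +
               0.4 * exp(-(tt - (centre + 250))^2 / (2 * 40^2)))
  }
  v2 <- beat(ref_ms)
  if (ref_ms - rr_ms > 100) v2 <- v2 + beat(ref_ms - rr_ms, scale = 0.9)
  v2
}

#' Generate a complete synthetic HDEAM study with ground truth
#'
#' Samples `n_points` sites area-uniformly on the mesh, evaluates the
#' supplied spatial fields at each site, and builds a unipolar electrogram
#' per site with [make_unipolar_egm()]'s waveform model plus a shared
#' synthetic V2 surface lead whose amplitude minimum sits exactly at the
#' reference annotation. The J-point used for the J-elevation ground truth
#' is the one [detect_jpoint()] finds on that V2 lead, so the generator and
#' the pipeline agree on the study J-point by construction.
#'
#' @param mesh an [epm_mesh()], e.g. from [make_rv_mesh()].
#' @param n_points number of electro-anatomical points (>= 1).
#' @param at_field,ari_field,jel_field scalar fields: either a single
#'   number or a function taking an n x 3 coordinate matrix and returning n
#'   values (ms, ms, mV respectively).
#' @param fs sampling rate (Hz).
#' @param noise_sd white-noise SD added to the unipolar traces (mV).
#' @param seed integer seed; the study is fully reproducible given it.
#' @param reference_annotation,woi timing metadata (ms); defaults 2000 and
#'   (-100, 100).
#' @param duration_ms trace duration (ms).
#' @param rs_amp_mv,t_amp_mv electrogram template amplitudes (mV).
#' @param force_range range of the uniform contact-force distribution
#'   (grams); the default 2--30 g deliberately straddles the 5--25 g
#'   acceptance filter.
#' @param phase_label phase tag stored in the study.
#' @return A list with `study` (an [epm_study()]) and `truth`, a ground
#'   truth object holding per-point `at_ms`, `ari_ms`, `jel_mv`, the study
#'   `jpoint_sample`, `rr_ms`, and the generator settings needed to build a
#'   matched post-phase study.
#' @export
make_study <- function(mesh, n_points,
                       at_field = 20, ari_field = 250, jel_field = 0.5,
                       fs = 1000, noise_sd = 0, seed = 1,
                       reference_annotation = 2000, woi = c(-100, 100),
                       duration_ms = reference_annotation + 700,
                       rs_amp_mv = 2, t_amp_mv = 1,
                       force_range = c(2, 30), phase_label = "pre") {
  if (n_points < 1) stop("n_points must be >= 1")
  set.seed(seed)
  pts <- sample_surface_points(mesh, n_points)
  centre <- colMeans(mesh$vertices)
  dir <- pts - matrix(centre, n_points, 3, byrow = TRUE)
  dir <- dir / sqrt(rowSums(dir^2))
  pos <- pts + dir * runif(n_points, 0, 0.5)   # catheter sits just off-surface

  eval_field <- function(f, where) {
    if (is.function(f)) as.numeric(f(where)) else rep(as.numeric(f), nrow(where))
  }
  # timing fields are snapped to the sampling grid: the ground-truth
  # fiducials are defined in samples, so +-1-sample recovery is meaningful
  snap <- function(ms) round(ms * fs / 1000) * 1000 / fs
  at <- snap(eval_field(at_field, pts))
  ari <- snap(eval_field(ari_field, pts))
  jel <- eval_field(jel_field, pts)
  if (any(ari <= 0)) stop("ari_field must be positive everywhere")

  n_samp <- round(duration_ms * fs / 1000) + 1
  v2 <- make_v2_trace(fs, reference_annotation, n_samp)
  search <- c(ms_to_sample(reference_annotation + woi[1], fs),
              min(n_samp, ms_to_sample(reference_annotation + woi[2] + 100, fs)))
  jp <- detect_jpoint(v2, fs, search = search)
  t_j_ms <- (jp - 1) * 1000 / fs

  tt <- (seq_len(n_samp) - 1) * 1000 / fs
  uni <- egm_bank_clean(tt, reference_annotation + at, ari, jel, t_j_ms,
                        rs_amp_mv, t_amp_mv)
  if (noise_sd > 0)
    uni <- uni + matrix(rnorm(length(uni), 0, noise_sd), nrow(uni))

  force <- runif(n_points, force_range[1], force_range[2])
  study <- epm_study(mesh, positions = pos, surface_positions = pts,
                     unipolar = uni, contact_force = force,
                     ecg = list(V2 = v2), sampling_rate = fs,
                     reference_annotation = reference_annotation,
                     woi = woi, phase_label = phase_label)
  truth <- structure(list(at_ms = at, ari_ms = ari, jel_mv = jel,
                          jpoint_sample = jp, rr_ms = 1000,
                          fields = list(at = at_field, ari = ari_field,
                                        jel = jel_field),
                          fs = fs, reference_annotation = reference_annotation,
                          woi = woi, duration_ms = duration_ms,
                          rs_amp_mv = rs_amp_mv, t_amp_mv = t_amp_mv,
                          noise_sd = noise_sd, seed = seed),
                     class = "epm_truth")
  list(study = study, truth = truth)
}

#' Derive a post-challenge study from a pre-challenge one
#'
#' Emulates the second acquisition of a drug-challenge protocol: each
#' pre-phase point is dropped independently with probability `dropout`
#' (default 0.36, the average map point loss between the two phases),
#' surviving positions are perturbed by isotropic jitter and re-projected
#' onto the surface, and the electrograms are regenerated with the spatial
#' fields shifted by `delta_fields`.
#'
#' @param pre result of [make_study()] (list with `study` and `truth`), or
#'   an `epm_study` together with its truth in `truth`.
#' @param delta_fields named list with any of `at`, `ari`, `jel`: constants
#'   or functions of position added to the corresponding field.
#' @param dropout per-point drop probability in `[0, 1)`.
#' @param jitter_mm isotropic positional jitter SD (mm) applied before
#'   re-projection.
#' @param seed integer seed.
#' @param truth ground truth of the pre study when `pre` is a bare
#'   `epm_study`.
#' @return A list with `pre`, `post` (both [epm_study()]) and `truth`; the
#'   post truth records the surviving `pre_index` map and the per-point
#'   `deltas` actually applied.
#' @export
make_pre_post <- function(pre, delta_fields = list(), dropout = 0.36,
                          jitter_mm = 1, seed = 1, truth = NULL) {
  if (is.list(pre) && !inherits(pre, "epm_study") &&
      all(c("study", "truth") %in% names(pre))) {
    truth <- pre$truth; pre <- pre$study
  }
  if (is.null(truth)) stop("ground truth of the pre study is required")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (jitter_mm < 0) stop("jitter_mm must be >= 0")
  set.seed(seed)
  n <- n_points(pre)
  keep <- which(runif(n) >= dropout)
  m <- length(keep)

  pts <- pre$surface_positions[keep, , drop = FALSE]
  if (jitter_mm > 0 && m > 0) {
    pts <- pts + matrix(rnorm(3 * m, 0, jitter_mm), m, 3)
    proj <- project_to_surface(pts, pre$mesh)
    pts <- matrix(as.numeric(proj), m, 3)
  }

  eval_field <- function(f, where, default = 0) {
    if (is.null(f)) rep(default, nrow(where))
    else if (is.function(f)) as.numeric(f(where))
    else rep(as.numeric(f), nrow(where))
  }
  base <- lapply(truth$fields, function(f)
    if (is.function(f)) as.numeric(f(pts)) else rep(as.numeric(f), m))
  fs <- truth$fs
  snap <- function(ms) round(ms * fs / 1000) * 1000 / fs
  at_post <- snap(base$at + eval_field(delta_fields$at, pts))
  ari_post <- snap(base$ari + eval_field(delta_fields$ari, pts))
  jel_post <- base$jel + eval_field(delta_fields$jel, pts)
  n_samp <- round(truth$duration_ms * fs / 1000) + 1
  v2 <- make_v2_trace(fs, truth$reference_annotation, n_samp)
  jp <- truth$jpoint_sample
  t_j_ms <- (jp - 1) * 1000 / fs
  tt <- (seq_len(n_samp) - 1) * 1000 / fs
  uni <- egm_bank_clean(tt, truth$reference_annotation + at_post, ari_post,
                        jel_post, t_j_ms, truth$rs_amp_mv, truth$t_amp_mv)
  if (truth$noise_sd > 0)
    uni <- uni + matrix(rnorm(length(uni), 0, truth$noise_sd), nrow(uni))

  centre <- colMeans(pre$mesh$vertices)
  dirm <- pts - matrix(centre, m, 3, byrow = TRUE)
  nrm <- sqrt(rowSums(dirm^2)); nrm[nrm == 0] <- 1
  pos <- pts + dirm / nrm * runif(m, 0, 0.5)

  post <- epm_study(pre$mesh, positions = pos, surface_positions = pts,
                    unipolar = uni,
                    contact_force = pre$contact_force[keep],
                    ecg = list(V2 = v2), sampling_rate = fs,
                    reference_annotation = truth$reference_annotation,
                    woi = truth$woi, phase_label = "post")
  post_truth <- structure(list(at_ms = at_post, ari_ms = ari_post,
                               jel_mv = jel_post, jpoint_sample = jp,
                               rr_ms = truth$rr_ms,
                               pre_index = keep,
                               deltas = list(at = at_post - truth$at_ms[keep],
                                             ari = ari_post - truth$ari_ms[keep],
                                             jel = jel_post - truth$jel_mv[keep]),
                               seed = seed),
                          class = "epm_truth")
  list(pre = pre, post = post, truth = list(pre = truth, post = post_truth))
}
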