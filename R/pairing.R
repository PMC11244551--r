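#' Spatially pair post-phase points with pre-phase points
#'
#' For each post point the Euclidean-nearest pre point is identified
#' (distance ties break to the lowest pre index); pairs whose distance
#' exceeds `threshold_mm` (strictly) are excluded, so a pair exactly at
#' the threshold is retained. The default allows several post points to
#' share one pre point; `unique = TRUE` enforces one-to-one matching by
#' repeatedly selecting the globally minimum-distance pair and removing
#' both members (ties: smallest post index, then smallest pre index), so
#' the greedy selection distances are non-decreasing and the result is
#' fully deterministic.
#'
#' @param pre_positions n_pre x 3 matrix (mm).
#' @param post_positions n_post x 3 matrix (mm).
#' @param threshold_mm maximum pairing distance (default 5 mm).
#' @param unique logical: enforce one-to-one pairing.
#' @return data.frame with columns `post_idx`, `pre_idx`, `distance_mm`,
#'   ordered by `post_idx`.
#' @export
pair_points <- function(pre_positions, post_positions, threshold_mm = 5,
                        unique = FALSE) {
  pre <- as_xyz(pre_positions)
  post <- as_xyz(post_positions)
  if (nrow(pre) == 0L || nrow(post) == 0L)
    stop("both point sets must be non-empty")
  d <- sqrt(dist2_matrix(post, pre))        # n_post x n_pre
  # exact distance for a selected pair (the matrix form loses precision
  # through cancellation when points coincide)
  exact_d <- function(i, j)
    sqrt(rowSums((post[i, , drop = FALSE] - pre[j, , drop = FALSE])^2))
  if (!unique) {
    nn <- max.col(-d, ties.method = "first")
    dist <- exact_d(seq_len(nrow(post)), nn)
    keep <- dist <= threshold_mm
    out <- data.frame(post_idx = which(keep), pre_idx = nn[keep],
                      distance_mm = dist[keep])
  } else {
    out <- data.frame(post_idx = integer(0), pre_idx = integer(0),
                      distance_mm = numeric(0))
    repeat {
      mn <- suppressWarnings(min(d))
      if (!is.finite(mn) || mn > threshold_mm) break
      hit <- which(d == mn, arr.ind = TRUE)
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
      out <- rbind(out, data.frame(post_idx = hit[1], pre_idx = hit[2],
                                   distance_mm = exact_d(hit[1], hit[2])))
      d[hit[1], ] <- Inf
      d[, hit[2]] <- Inf
    }
    attr(out, "selection_distances") <- out$distance_mm
    out <- out[order(out$post_idx), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Pair two studies and assemble the differential container
#'
#' Convenience wrapper around [pair_points()] using the studies' surface
#' positions (the coordinates the maps are built from) or, optionally, the
#' raw catheter positions.
#'
#' @param pre,post [epm_study()] objects of the two phases.
#' @param threshold_mm maximum pairing distance (default 5 mm).
#' @param unique one-to-one pairing (see [pair_points()]).
#' @param use_surface pair on surface projections (default) or raw
#'   positions.
#' @return An object of class `epm_paired`: list with `pre`, `post`,
#'   `pairs`, `threshold_mm`.
#' @export
pair_studies <- function(pre, post, threshold_mm = 5, unique = FALSE,
                         use_surface = TRUE) {
  a <- if (use_surface) pre$surface_positions else pre$positions
  b <- if (use_surface) post$surface_positions else post$positions
  pairs <- pair_points(a, b, threshold_mm = threshold_mm, unique = unique)
  structure(list(pre = pre, post = post, pairs = pairs,
                 threshold_mm = threshold_mm),
            class = "epm_paired")
}

#' @export
print.epm_paired <- function(x, ...) {
  cat(sprintf("<epm_paired> %d pairs (threshold %g mm) from %d pre / %d post points\n",
              nrow(x$pairs), x$threshold_mm, n_points(x$pre), n_points(x$post)))
  invisible(x)
}

#' Per-pair feature differences and differential maps
#'
#' Computes `post - pre` for each paired point and each requested feature.
#' Pairs where either side was quality-rejected are dropped (their count
#' is reported with a message). When `post_study` is supplied, each delta
#' is also interpolated onto the post-phase mesh at the post surface
#' positions, yielding the variation maps used to assess drug-induced
#' changes.
#'
#' @param pre_features,post_features data.frames from [extract_features()]
#'   for the two phases.
#' @param pairs pairing table from [pair_points()]/[pair_studies()].
#' @param feature_names features to difference (default: the standard
#'   numeric features present on both sides).
#' @param post_study optional [epm_study()] of the post phase, for the
#'   delta maps.
#' @param method interpolation method for the delta maps.
#' @return List with `deltas` (data.frame: `post_idx`, `pre_idx`,
#'   `distance_mm`, one `delta_<feature>` column per feature, plus the
#'   count of quality-dropped pairs as attribute `n_rejected`) and `maps`
#'   (named list of `epm_feature_map`, empty when `post_study` is `NULL`).
#' @export
delta_features <- function(pre_features, post_features, pairs,
                           feature_names = NULL, post_study = NULL,
                           method = "nearest") {
  if (inherits(pairs, "epm_paired")) {
    if (is.null(post_study)) post_study <- pairs$post
    pairs <- pairs$pairs
  }
  standard <- c("uni_jel_mv", "at_ms", "ari_ms", "aric_ms", "uni_pp_mv")
  if (is.null(feature_names))
    feature_names <- intersect(standard,
                               intersect(names(pre_features), names(post_features)))
  missing_f <- setdiff(feature_names,
                       intersect(names(pre_features), names(post_features)))
  if (length(missing_f) > 0)
    stop("feature(s) absent from one side: ", paste(missing_f, collapse = ", "))

  ok_pre <- if ("quality" %in% names(pre_features)) pre_features$quality else TRUE
  ok_post <- if ("quality" %in% names(post_features)) post_features$quality else TRUE
  good <- ok_post[pairs$post_idx] & ok_pre[pairs$pre_idx]
  n_rej <- sum(!good)
  if (n_rej > 0)
    message(n_rej, " pair(s) dropped because one side was quality-rejected")
  kept <- pairs[good, , drop = FALSE]

  deltas <- kept
  for (f in feature_names)
    deltas[[paste0("delta_", f)]] <-
      post_features[[f]][kept$post_idx] - pre_features[[f]][kept$pre_idx]
  rownames(deltas) <- NULL
  attr(deltas, "n_rejected") <- n_rej

  maps <- list()
  if (!is.null(post_study) && nrow(kept) > 0) {
    pos <- post_study$surface_positions[kept$post_idx, , drop = FALSE]
    for (f in feature_names) {
      nm <- paste0("delta_", f)
      maps[[nm]] <- interpolate_feature(pos, deltas[[nm]], post_study$mesh,
                                        method = method, name = nm)
    }
  }
  list(deltas = deltas, maps = maps)
}
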