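#' Threshold condition on a feature
#'
#' A named predicate applied vertex-wise to a parametric map, e.g.
#' "unipolar voltage <= 4.4 mV" or "delta Uni-JEl within 0.5..1.5 mV".
#'
#' @param feature feature name the condition applies to.
#' @param op one of `"lt"`, `"le"`, `"gt"`, `"ge"`, `"within"`.
#' @param value threshold (lower bound for `"within"`).
#' @param value2 upper bound for `"within"` (must be >= `value`).
#' @return An object of class `epm_condition`.
#' @export
epm_condition <- function(feature, op = c("lt", "le", "gt", "ge", "within"),
                          value, value2 = NULL) {
  op <- match.arg(op)
  if (op == "within") {
    if (is.null(value2) || value2 < value)
      stop("'within' needs value <= value2")
  }
  structure(list(feature = feature, op = op, value = value, value2 = value2),
            class = "epm_condition")
}

#' @export
print.epm_condition <- function(x, ...) {
  sym <- c(lt = "<", le = "<=", gt = ">", ge = ">=", within = "within")[x$op]
  rhs <- if (x$op == "within") sprintf("[%g, %g]", x$value, x$value2)
         else sprintf("%g", x$value)
  cat(sprintf("<epm_condition> %s %s %s\n", x$feature, sym, rhs))
  invisible(x)
}

# Vertex-wise predicate; missing values never satisfy a condition.
condition_satisfied <- function(values, condition) {
  ok <- switch(condition$op,
               lt = values < condition$value,
               le = values <= condition$value,
               gt = values > condition$value,
               ge = values >= condition$value,
               within = values >= condition$value & values <= condition$value2)
  ok & !is.na(values)
}

#' Surface area where a condition holds
#'
#' Sums the areas of the triangles whose vertices satisfy the condition on
#' the interpolated vertex field, and reports the result both in mm^2 and
#' as a percentage of the total mesh area. The default (conservative)
#' discretization counts a triangle only when all three of its vertices
#' satisfy the condition; `rule = "majority"` requires two of three.
#' Missing vertices never satisfy a condition.
#'
#' @param mesh an [epm_mesh()].
#' @param vertex_field per-vertex values (or an `epm_feature_map`).
#' @param condition an [epm_condition()].
#' @param rule `"all"` (default) or `"majority"` triangle inclusion rule.
#' @return Named numeric vector `c(area_mm2, area_pct)`.
#' @export
area_where <- function(mesh, vertex_field, condition, rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (inherits(vertex_field, "epm_feature_map"))
    vertex_field <- vertex_field$vertex_field
  if (length(vertex_field) != nrow(mesh$vertices))
    stop("vertex_field length must equal the vertex count")
  ok <- condition_satisfied(vertex_field, condition)
  need <- if (rule == "all") 3L else 2L
  hit <- rowSums(matrix(ok[mesh$triangles], ncol = 3)) >= need
  areas <- triangle_areas(mesh)
  a <- sum(areas[hit])
  c(area_mm2 = a, area_pct = 100 * a / sum(areas))
}

#' Surface area where two conditions hold jointly
#'
#' A triangle is counted when its vertices satisfy both conditions
#' (logical AND of the two per-vertex predicates), quantifying e.g. the
#' region where Uni-JEl and AT are simultaneously abnormal.
#'
#' @param mesh an [epm_mesh()].
#' @param field_a,field_b per-vertex values (or `epm_feature_map`s) on the
#'   same mesh.
#' @param cond_a,cond_b [epm_condition()]s for the two fields.
#' @param rule triangle inclusion rule, as in [area_where()].
#' @return Named numeric vector `c(area_mm2, area_pct)`.
#' @export
area_where_joint <- function(mesh, field_a, cond_a, field_b, cond_b,
                             rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (inherits(field_a, "epm_feature_map")) field_a <- field_a$vertex_field
  if (inherits(field_b, "epm_feature_map")) field_b <- field_b$vertex_field
  if (length(field_a) != nrow(mesh$vertices) ||
      length(field_b) != nrow(mesh$vertices))
    stop("both fields must live on the same mesh")
  ok <- condition_satisfied(field_a, cond_a) & condition_satisfied(field_b, cond_b)
  need <- if (rule == "all") 3L else 2L
  hit <- rowSums(matrix(ok[mesh$triangles], ncol = 3)) >= need
  areas <- triangle_areas(mesh)
  a <- sum(areas[hit])
  c(area_mm2 = a, area_pct = 100 * a / sum(areas))
}

#' Two-valued field marking where a condition holds
#'
#' 1 where the condition is satisfied, 0 elsewhere, missing preserved;
#' intended for the two-colour rendering of threshold areas via
#' [export_vtk()].
#'
#' @param vertex_field per-vertex values (or an `epm_feature_map`).
#' @param condition an [epm_condition()].
#' @return Numeric vector of 0/1/`NA`.
#' @export
binary_field <- function(vertex_field, condition) {
  if (inherits(vertex_field, "epm_feature_map"))
    vertex_field <- vertex_field$vertex_field
  out <- as.numeric(condition_satisfied(vertex_field, condition))
  out[is.na(vertex_field)] <- NA_real_
  out
}

#' Summary statistics of a feature sample
#'
#' Mean, median, SD (n-1 denominator), interquartile range (quartiles by
#' linear interpolation, R type 7) and range (max - min), the dispersion
#' markers used to characterise heterogeneity. For n = 1 the SD is
#' reported missing; for n = 0 all statistics are missing.
#'
#' @param values numeric vector (NAs dropped).
#' @param label row label.
#' @return One-row data.frame: `label`, `n`, `mean`, `median`, `sd`,
#'   `iqr`, `range`.
#' @export
summarize_stats <- function(values, label = "") {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L)
    return(data.frame(label = label, n = 0L, mean = NA_real_,
                      median = NA_real_, sd = NA_real_, iqr = NA_real_,
                      range = NA_real_, stringsAsFactors = FALSE))
  data.frame(label = label, n = n,
             mean = mean(values),
             median = stats::median(values),
             sd = if (n > 1) stats::sd(values) else NA_real_,
             iqr = stats::IQR(values, type = 7),
             range = max(values) - min(values),
             stringsAsFactors = FALSE)
}

#' Right-ventricular activation time (RVAT)
#'
#' Total activation duration of the map: the spread (max - min) of the
#' accepted local activation times.
#'
#' @param at_values activation times in ms (NAs dropped).
#' @return RVAT in ms.
#' @export
rvat <- function(at_values) {
  at_values <- at_values[!is.na(at_values)]
  if (length(at_values) < 2L) stop("rvat needs at least 2 activation times")
  max(at_values) - min(at_values)
}

#' Example voltage-abnormality presets
#'
#' The two unipolar peak-to-peak voltage thresholds used as example
#' abnormality conditions (<= 4.4 mV and <= 5.3 mV); on any field the
#' <= 5.3 mV area contains the <= 4.4 mV area.
#'
#' @return Named list of [epm_condition()]s.
#' @export
preset_conditions <- function() {
  list(uni_le_4p4 = epm_condition("uni_pp_mv", "le", 4.4),
       uni_le_5p3 = epm_condition("uni_pp_mv", "le", 5.3))
}

#' Threshold recipe: median of a differential feature inside a ROI
#'
#' Computes the data-driven threshold used for two-colour variation maps:
#' the median of the paired feature differences restricted to a region of
#' interest (e.g. median delta Uni-JEl in the RVOT), returned as a
#' ready-to-use `>=` condition. The threshold is a per-study quantity, not
#' a constant.
#'
#' @param delta_values per-pair feature differences inside the ROI.
#' @param feature feature name for the resulting condition.
#' @return An [epm_condition()] `feature >= median(delta_values)`.
#' @export
roi_median_condition <- function(delta_values, feature) {
  delta_values <- delta_values[!is.na(delta_values)]
  if (length(delta_values) == 0L) stop("no delta values supplied")
  epm_condition(feature, "ge", stats::median(delta_values))
}

REPORT_FEATURES <- c("uni_jel_mv", "at_ms", "ari_ms", "aric_ms", "uni_pp_mv")

#' Build the study report table
#'
#' One row per (study x region x feature) with the summary statistics of
#' [summarize_stats()] plus, for each supplied condition matching the
#' row's feature, the threshold area of the interpolated map in mm^2 and
#' as a percent of the total surface. Global rows carry the region label
#' `"ALL"`. The column order is fixed and the output is deterministic, so
#' repeated runs on the same inputs are byte-identical.
#'
#' @param studies named list of [epm_study()] objects.
#' @param rois named list of [define_roi()] results (may be empty).
#' @param conditions named list of [epm_condition()]s (may be empty).
#' @param path optional CSV output path.
#' @param config an [feature_config()].
#' @param features data.frames from [extract_features()], one per study,
#'   computed on the fly when `NULL`.
#' @return The report data.frame (invisibly written to `path` when given).
#' @export
build_report <- function(studies, rois = list(), conditions = list(),
                         path = NULL, config = feature_config(),
                         features = NULL) {
  if (inherits(studies, "epm_study")) studies <- list(study = studies)
  if (is.null(names(studies)))
    names(studies) <- paste0("study", seq_along(studies))
  if (is.null(features))
    features <- lapply(studies, extract_features, config = config)

  rows <- list()
  for (s in names(studies)) {
    study <- studies[[s]]
    feats <- features[[s]]
    regions <- c(list(ALL = NULL), rois)
    for (r in names(regions)) {
      roi <- regions[[r]]
      mask <- if (is.null(roi)) rep(TRUE, n_points(study))
              else roi_membership(roi, study)
      for (f in REPORT_FEATURES) {
        vals <- feats[[f]]
        ok <- mask & (if (f %in% c("ari_ms", "aric_ms")) feats$quality else TRUE)
        st <- summarize_stats(vals[ok], label = f)
        row <- data.frame(study = s, roi = r, feature = f,
                          n = st$n, mean = st$mean, median = st$median,
                          sd = st$sd, iqr = st$iqr, range = st$range,
                          stringsAsFactors = FALSE)
        for (cn in names(conditions)) {
          cond <- conditions[[cn]]
          if (cond$feature == f && sum(ok) > 0) {
            fm <- if (is.null(roi))
              interpolate_feature(study$surface_positions[ok, , drop = FALSE],
                                  vals[ok], study$mesh, name = f)
            else restrict_and_reinterpolate(study, roi, ifelse(ok, vals, NA),
                                            name = f)
            aw <- area_where(study$mesh, fm$vertex_field, cond)
            row[[paste0("area_mm2_", cn)]] <- aw[["area_mm2"]]
            row[[paste0("area_pct_", cn)]] <- aw[["area_pct"]]
          } else {
            row[[paste0("area_mm2_", cn)]] <- NA_real_
            row[[paste0("area_pct_", cn)]] <- NA_real_
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(path))
    utils::write.csv(report, path, row.names = FALSE, eol = "\n", na = "")
  invisible(report)
}
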