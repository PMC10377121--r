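#' Kruskal-Wallis rank test across groups
#'
#' Rank-based k-sample test with tie correction (H statistic, chi-square
#' p-value on k - 1 degrees of freedom), computed by `stats::kruskal.test`.
#' The fully degenerate case where every observation across all groups is
#' identical is reported as H = 0, p = 1.
#'
#' @param groups Named or unnamed list of numeric vectors, each nonempty;
#'   at least two groups.
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L)
    lm_abort("need at least two groups", "lesionmap_error_bad_params")
  if (any(vapply(groups, length, 0L) < 1L))
    lm_abort("every group needs at least one observation",
             "lesionmap_error_empty_group")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  kt <- stats::kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Pairwise Kruskal-Wallis comparisons
#'
#' One two-group Kruskal-Wallis test per requested pair. Unadjusted p-values
#' are the primary output (matching common reporting practice for these
#' comparisons); a Holm-adjusted column is also emitted, clearly labeled.
#'
#' @param groups Named list of numeric vectors.
#' @param pairs List of length-2 character vectors of group names; default
#'   all pairs.
#' @return data.frame with columns group_a, group_b, statistic, p_value,
#'   p_holm.
#' @export
pairwise_compare <- function(groups, pairs = NULL) {
  nm <- names(groups)
  if (is.null(nm)) lm_abort("groups must be named",
                            "lesionmap_error_bad_params")
  if (is.null(pairs)) {
    cmb <- utils::combn(nm, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  rows <- lapply(pairs, function(p) {
    if (!all(p %in% nm))
      lm_abort(sprintf("unknown group name in pair (%s)",
                       paste(p, collapse = ", ")),
               "lesionmap_error_unknown_group")
    kt <- kruskal_wallis(groups[p])
    data.frame(group_a = p[1], group_b = p[2], statistic = kt$statistic,
               p_value = kt$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- p.adjust(out$p_value, method = "holm")
  out
}

#' Per-group descriptive summaries of lesion features
#'
#' Mean, SD and median per group for the standard lesion features (tumor
#' count per patient, tumor size, depth, edema/tumor ratio), from the metrics
#' table of [compute_lesion_metrics()]. Depth is conventionally reported as a
#' median, the others as mean +/- SD; all three statistics are emitted for
#' every feature. Groups with a single observation carry `degenerate = TRUE`
#' (SD undefined).
#'
#' @param metrics Metrics data.frame with at least columns patient_id, group,
#'   tumor_volume_cm3, depth_mm, edema_tumor_ratio.
#' @return data.frame with one row per group x feature.
#' @export
summarize_features <- function(metrics) {
  if (nrow(metrics) == 0L)
    lm_abort("empty metrics table", "lesionmap_error_empty_input")
  counts <- stats::aggregate(lesion_id ~ patient_id + group, metrics, length)
  feature_values <- list(
    n_tumors_per_patient = split(counts$lesion_id, counts$group),
    tumor_volume_cm3 = split(metrics$tumor_volume_cm3, metrics$group),
    depth_mm = split(metrics$depth_mm, metrics$group),
    edema_tumor_ratio = split(metrics$edema_tumor_ratio, metrics$group)
  )
  rows <- list()
  for (feat in names(feature_values)) {
    for (grp in names(feature_values[[feat]])) {
      v <- feature_values[[feat]][[grp]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, feature = feat, n = length(v), mean = mean(v),
        sd = if (length(v) > 1L) sd(v) else NA_real_,
        median = median(v), degenerate = length(v) == 1L)
    }
  }
  do.call(rbind, rows)
}

#' Group comparison table for lesion features
#'
#' Runs the three-group Kruskal-Wallis test, one-way ANOVA, and all pairwise
#' Kruskal-Wallis comparisons for each lesion feature, mirroring the standard
#' cohort-comparison layer. Both omnibus tests are emitted side by side.
#'
#' @param metrics Metrics data.frame (see [summarize_features()]).
#' @return List with `summary` (descriptives), `omnibus` (per-feature H,
#'   Kruskal-Wallis p, ANOVA F and p), `pairwise` (per-feature pairwise
#'   table).
#' @export
compare_groups <- function(metrics) {
  counts <- stats::aggregate(lesion_id ~ patient_id + group, metrics, length)
  feature_values <- list(
    n_tumors_per_patient = split(counts$lesion_id, counts$group),
    tumor_volume_cm3 = split(metrics$tumor_volume_cm3, metrics$group),
    depth_mm = split(metrics$depth_mm, metrics$group),
    edema_tumor_ratio = split(metrics$edema_tumor_ratio, metrics$group)
  )
  omnibus <- list()
  pairwise <- list()
  for (feat in names(feature_values)) {
    gr <- lapply(feature_values[[feat]], function(v) v[!is.na(v)])
    gr <- gr[vapply(gr, length, 0L) > 0L]
    if (length(gr) < 2L) next
    kw <- kruskal_wallis(gr)
    vals <- unlist(gr, use.names = FALSE)
    fac <- factor(rep(names(gr), vapply(gr, length, 0L)))
    an <- if (length(unique(vals)) > 1L && all(table(fac) > 1L)) {
      a <- summary(stats::aov(vals ~ fac))[[1]]
      c(a$`F value`[1], a$`Pr(>F)`[1])
    } else c(NA_real_, NA_real_)
    omnibus[[feat]] <- data.frame(
      feature = feat, kw_H = kw$statistic, kw_p = kw$p_value,
      anova_F = an[1], anova_p = an[2])
    pw <- pairwise_compare(gr)
    pw$feature <- feat
    pairwise[[feat]] <- pw
  }
  list(summary = summarize_features(metrics),
       omnibus = do.call(rbind, omnibus),
       pairwise = do.call(rbind, pairwise))
}
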