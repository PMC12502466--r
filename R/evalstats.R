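# Evaluation suite: overlap, volumetry adjustments, reliability statistics,
# group discrimination and segmentation-quality rejection arithmetic.

#' Dice similarity coefficient for one label
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [label_map()]s or integer arrays on the same grid.
#' @param label label code to compare.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b, label) {
  va <- if (inherits(a, "label_map")) a$labels else a
  vb <- if (inherits(b, "label_map")) b$labels else b
  if (!all(dim(va) == dim(vb))) stopf("label maps must share one grid")
  na <- sum(va == label); nb <- sum(vb == label)
  if (na + nb == 0L) return(1.0)
  2 * sum(va == label & vb == label) / (na + nb)
}

#' Mean Dice over the foreground labels present in a reference
#'
#' @param pred,ref label maps; `labels` the codes to average over (defaults
#'   to the gray-matter codes present in `ref`).
#' @return Scalar mean Dice.
#' @export
mean_foreground_dice <- function(pred, ref, labels = NULL) {
  vr <- if (inherits(ref, "label_map")) ref$labels else ref
  if (is.null(labels))
    labels <- intersect(unname(mtl_gm_labels()), unique(as.vector(vr)))
  mean(vapply(labels, function(l) dice(pred, ref, l), numeric(1)))
}

#' Per-region volumes from a label map
#'
#' Volume = voxel count x voxel volume, for every gray-matter label.
#'
#' @param labels a [label_map()].
#' @param spacing voxel spacing in mm (taken from the label map by default).
#' @return Data frame with `region`, `value` (mm^3) and an `empty` flag.
#' @export
subregion_volumes <- function(labels, spacing = NULL) {
  spacing <- spacing %||% labels$spacing
  if (any(spacing <= 0)) stopf("spacing must be positive")
  vv <- prod(spacing)
  arr <- if (inherits(labels, "label_map")) labels$labels else labels
  gm <- mtl_gm_labels()
  counts <- vapply(gm, function(l) sum(arr == l), numeric(1))
  empty <- counts == 0
  if (any(empty))
    warning("empty label(s): ", paste(names(gm)[empty], collapse = ", "),
            call. = FALSE)
  data.frame(region = names(gm), value = unname(counts) * vv,
             empty = unname(empty), row.names = NULL)
}

#' Tail adjustment of hippocampal subfield volumes
#'
#' The posterior hippocampal tail is not partitioned into subfields, so each
#' subfield volume is rescaled by `R = (sum(subfields) + Tail) /
#' sum(subfields)`; the Tail itself is dropped from downstream analysis. The
#' adjusted subfields sum exactly to the total hippocampal volume.
#'
#' @param volumes named numeric vector containing at least CA1, CA2, CA3,
#'   DG, SUB and Tail.
#' @return Named vector of adjusted subfield volumes (no Tail entry).
#' @export
tail_adjust <- function(volumes) {
  sf <- hippo_subfields()
  if (!all(c(sf, "Tail") %in% names(volumes)))
    stopf("volumes must contain %s and Tail", paste(sf, collapse = ", "))
  s <- sum(volumes[sf])
  if (s <= 0) stopf("subfield volume sum must be positive")
  r <- (s + volumes[["Tail"]]) / s
  volumes[sf] * r
}

#' Anterior-posterior length normalization of cortical volumes
#'
#' Cortical subregion volumes are divided by the physical A-P extent (mm) of
#' the region's label support, yielding an area-like quantity comparable
#' across participants. The extent is `(max_slice - min_slice + 1)` times the
#' A-P slice spacing.
#'
#' @param volumes named numeric vector of cortical region volumes (mm^3).
#' @param labels a [label_map()] providing the label support.
#' @param spacing voxel spacing (defaults to the label map's).
#' @return Named vector of normalized values (mm^2).
#' @export
ap_normalize <- function(volumes, labels, spacing = NULL) {
  spacing <- spacing %||% labels$spacing
  arr <- if (inherits(labels, "label_map")) labels$labels else labels
  ap <- axis_index(labels, "AP")
  L <- mtl_labels()
  out <- volumes
  for (rn in names(volumes)) {
    code <- L[[rn]]
    sl <- apply(arr == code, ap, any)
    if (!any(sl)) stopf("region %s has zero A-P extent", rn)
    extent <- (max(which(sl)) - min(which(sl)) + 1) * spacing[ap]
    out[[rn]] <- volumes[[rn]] / extent
  }
  out
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement; the
#' standard test-retest reliability coefficient. Computed from the ANOVA
#' mean squares of the subjects x measurements table.
#'
#' @param pairs two-column matrix or data frame, one row per subject,
#'   columns = the two measurements.
#' @return List with `icc` and a `degenerate` flag (zero between-subject
#'   variance).
#' @export
icc_consistency <- function(pairs) {
  m <- as.matrix(pairs)
  if (ncol(m) < 2L || nrow(m) < 3L) stopf("need >= 3 subjects, >= 2 measurements")
  n <- nrow(m); k <- ncol(m)
  row_m <- rowMeans(m); col_m <- colMeans(m); g <- mean(m)
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- msr <= .Machine$double.eps * max(1, g^2)
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  list(icc = icc, degenerate = degenerate)
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are `t2 - t1`; limits of agreement are the mean difference
#' +/- 1.96 sample standard deviations (n-1 denominator).
#'
#' @param pairs two-column matrix/data frame (t1, t2).
#' @return A `bland_altman` list: `mean_diff`, `sd_diff`, `lower`, `upper`.
#' @export
bland_altman <- function(pairs) {
  m <- as.matrix(pairs)
  if (nrow(m) < 2L) stopf("need >= 2 pairs")
  d <- m[, 2] - m[, 1]
  md <- mean(d); s <- sd(d)
  structure(list(mean_diff = md, sd_diff = s,
                 lower = md - 1.96 * s, upper = md + 1.96 * s),
            class = "bland_altman")
}

#' Covariate-adjusted group discrimination for one region
#'
#' Fits the linear model `value ~ group + covariates` (age and ICV for
#' volumes, age only for thickness) and reports the two-sided p-value of the
#' group coefficient, the AUC and Cohen's d computed on covariate-residualized
#' values. AUC is the probability that a random control (A-CU) exceeds a
#' random patient (A+MCI); it is never orientation-flipped, so values below
#' 0.5 are possible. Cohen's d is the control-minus-patient difference of
#' residualized means over the pooled SD.
#'
#' @param table long measurement table with columns `region`, `measure_kind`,
#'   `value`, `group`, `age`, `icv`, and optionally `side`/`subject`.
#' @param region region name to test.
#' @param measure_kind `"volume"` or `"thickness"`.
#' @return List with `p`, `auc`, `cohens_d`, `n`.
#' @export
glm_discriminate <- function(table, region, measure_kind = "volume") {
  d <- table[table$region == region & table$measure_kind == measure_kind, ]
  if (!all(c("A-CU", "A+MCI") %in% d$group))
    stopf("both diagnostic groups must be present")
  if (min(table(d$group)) < 3L) stopf("need >= 3 members per group")
  d$grp <- factor(d$group, levels = c("A-CU", "A+MCI"))
  covs <- if (measure_kind == "volume") c("age", "icv") else "age"
  f_full <- stats::reformulate(c("grp", covs), response = "value")
  fit <- lm(f_full, data = d)
  cf <- summary(fit)$coefficients
  if (!"grpA+MCI" %in% rownames(cf)) stopf("singular design")
  p <- cf["grpA+MCI", 4]
  # residualize on covariates only (pooled fit), then compare groups
  res <- stats::residuals(lm(stats::reformulate(covs, response = "value"),
                             data = d))
  r_cu <- res[d$grp == "A-CU"]; r_pt <- res[d$grp == "A+MCI"]
  n1 <- length(r_cu); n2 <- length(r_pt)
  pooled <- sqrt(((n1 - 1) * var(r_cu) + (n2 - 1) * var(r_pt)) / (n1 + n2 - 2))
  cohens_d <- (mean(r_cu) - mean(r_pt)) / pooled
  rk <- rank(c(r_cu, r_pt))
  auc <- (sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  list(p = unname(p), auc = auc, cohens_d = cohens_d, n = c(n1, n2))
}

#' Aggregate three quality ratings into a final rating
#'
#' The three 1-9 ratings are averaged and rounded to the nearest integer
#' (half away from zero; means of three integers are never exactly .5).
#' A final rating >= 5 counts as high quality.
#'
#' @param ratings three integers in 1..9.
#' @return A `quality_rating` list: `ratings`, `final`, `is_high`.
#' @export
quality_aggregate <- function(ratings) {
  if (length(ratings) != 3L || any(is.na(ratings)) ||
      any(ratings < 1 | ratings > 9) || any(ratings != round(ratings)))
    stopf("need three integer ratings in 1..9")
  final <- as.integer(round_away(mean(ratings), 0))
  structure(list(ratings = as.integer(ratings), final = final,
                 is_high = final >= 5L),
            class = "quality_rating")
}

#' Summarize the quality composition of a cohort split
#'
#' @param ratings vector of final per-ROI ratings (1-9), or a list of
#'   [quality_aggregate()] results.
#' @param split label for the split being summarized.
#' @return List with `split`, `n_high`, `n_low`, `pct_low` (rounded to 2
#'   decimals, half away from zero).
#' @export
cohort_quality_summary <- function(ratings, split = "test") {
  if (is.list(ratings))
    ratings <- vapply(ratings, function(r) r$final, numeric(1))
  if (any(is.na(ratings))) stopf("every ROI must be rated")
  n_high <- sum(ratings >= 5); n_low <- sum(ratings < 5)
  list(split = split, n_high = n_high, n_low = n_low,
       pct_low = round_away(100 * n_low / (n_high + n_low), 2))
}

#' Qualitative segmentation confusion matrix
#'
#' 3x3 counts of good/uncertain/bad ratings with the single-modality model on
#' rows and the multi-modality model on columns.
#'
#' @param counts 3x3 non-negative matrix (rows/cols ordered good, uncertain,
#'   bad).
#' @return A `qual_confusion` matrix.
#' @export
qual_confusion <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(3, 3)) || any(m < 0) || any(m != round(m)))
    stopf("confusion matrix must be 3x3 non-negative counts")
  dimnames(m) <- list(single = c("good", "uncertain", "bad"),
                      multi = c("good", "uncertain", "bad"))
  structure(m, class = c("qual_confusion", "matrix"))
}

#' Rejection rates and their reduction from a quality confusion matrix
#'
#' Strict rejection counts both "uncertain" and "bad" segmentations; lenient
#' rejection counts only "bad". The reduction is the relative drop in
#' rejected segmentations from the single-modality to the multi-modality
#' model. All percentages are rounded to 2 decimals, half away from zero.
#'
#' @param cm a [qual_confusion()] (or 3x3 count matrix).
#' @return List with per-model strict/lenient rejection percentages and the
#'   strict/lenient reductions; `undefined` flags a zero single-modality
#'   rejection count.
#' @export
rejection_stats <- function(cm) {
  m <- unclass(qual_confusion(cm))
  total <- sum(m)
  single <- rowSums(m)   # counts by single-modality rating
  multi <- colSums(m)    # counts by multi-modality rating
  strict_s <- single[["uncertain"]] + single[["bad"]]
  strict_m <- multi[["uncertain"]] + multi[["bad"]]
  len_s <- single[["bad"]]
  len_m <- multi[["bad"]]
  pct <- function(x) round_away(100 * x / total, 2)
  red <- function(s, m) if (s == 0) NA_real_ else round_away(100 * (s - m) / s, 2)
  list(total = total,
       strict_single_pct = pct(strict_s), strict_multi_pct = pct(strict_m),
       lenient_single_pct = pct(len_s), lenient_multi_pct = pct(len_m),
       strict_reduction_pct = red(strict_s, strict_m),
       lenient_reduction_pct = red(len_s, len_m),
       undefined = strict_s == 0 || len_s == 0)
}
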