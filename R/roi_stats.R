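#' Tumor volume from caliper length and width
#'
#' Modified-ellipsoid formula `V = length * width^2 / 2` (mm^3), with length
#' the longest side and width the perpendicular. If width exceeds length the
#' two are swapped with a warning.
#'
#' @param length_mm,width_mm caliper measurements, mm (> 0). Vectorised.
#' @return volume, mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0))
    stop("caliper measurements must be > 0", call. = FALSE)
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length; swapping so that length is the longest side",
            call. = FALSE)
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  length_mm * width_mm^2 / 2
}

#' Tumor growth inhibition percentage
#'
#' `%TGI = (V_ctrl_dayX - V_trt_dayX) / (V_ctrl_dayX - V_ctrl_day0) * 100`;
#' values above 100% indicate shrinkage of treated tumors below their
#' baseline volume.
#'
#' @param v_ctrl_dayX control group volume at day X, mm^3.
#' @param v_trt_dayX treated group volume at day X, mm^3.
#' @param v_ctrl_day0 control group volume at baseline, mm^3.
#' @return percent.
#' @export
tgi <- function(v_ctrl_dayX, v_trt_dayX, v_ctrl_day0) {
  denom <- v_ctrl_dayX - v_ctrl_day0
  if (any(denom == 0))
    stop("control volume at day X equals baseline; TGI undefined",
         call. = FALSE)
  (v_ctrl_dayX - v_trt_dayX) / denom * 100
}

#' Signed percent change of a comparison value versus a reference
#'
#' `(comparison - reference) / reference * 100`.
#'
#' @param reference nonzero reference value. Vectorised.
#' @param comparison comparison value.
#' @return percent, signed.
#' @export
percent_change <- function(reference, comparison) {
  if (any(reference == 0))
    stop("`reference` must be nonzero", call. = FALSE)
  (comparison - reference) / reference * 100
}

#' Per-group summary of an animal-record table
#'
#' @param records data.frame with at least `group` (and optionally
#'   `timepoint`) plus the measure columns.
#' @param measures character vector of measure column names.
#' @return data.frame of group (x timepoint) cell mean, SD, and n per
#'   measure.
#' @export
group_summary <- function(records, measures) {
  by_cols <- intersect(c("group", "timepoint"), names(records))
  cells <- unique(records[by_cols])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- rep(TRUE, nrow(records))
    for (bc in by_cols) sel <- sel & records[[bc]] == cells[[bc]][i]
    for (m in measures) {
      v <- records[[m]][sel]
      v <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        cells[i, , drop = FALSE], measure = m,
        mean = mean(v), sd = stats::sd(v), n = length(v),
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Group comparison by Student t-test or two-way ANOVA
#'
#' `design = "two_sample"`: two-tailed Student t-test (equal variances)
#' between the two groups. `design = "two_way"`: two-way ANOVA with group,
#' timepoint, and their interaction, plus the cell-wise within-group
#' contrasts (paired comparisons across timepoints within each group and
#' between-group contrasts at each timepoint) that treatment studies report.
#' Significance threshold 0.05 throughout.
#'
#' @param records data.frame with `group`, the measure column, and (for the
#'   two-way design) `timepoint`.
#' @param measure measure column name.
#' @param design `"two_sample"` or `"two_way"`.
#' @return a list of class `group_comparison` with elements depending on the
#'   design: for `two_sample`, `statistic`, `p_value`, `df`, `group_means`;
#'   for `two_way`, `anova_table`, `contrasts` (data.frame of cell-wise
#'   t-tests).
#' @export
compare_groups <- function(records, measure,
                           design = c("two_sample", "two_way")) {
  design <- match.arg(design)
  if (!measure %in% names(records))
    stop(sprintf("measure column `%s` not found", measure), call. = FALSE)
  records <- records[is.finite(records[[measure]]), , drop = FALSE]
  groups <- unique(records$group)
  if (length(groups) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  check_cell <- function(sel, label) {
    if (sum(sel) < 2L)
      stop(sprintf("cell `%s` has fewer than 2 animals", label),
           call. = FALSE)
  }
  if (design == "two_sample") {
    for (g in groups) check_cell(records$group == g, g)
    tt <- stats::t.test(records[[measure]] ~ factor(records$group),
                        var.equal = TRUE)
    gm <- tapply(records[[measure]], records$group, mean)
    return(structure(list(
      design = design, measure = measure,
      statistic = unname(tt$statistic), p_value = tt$p.value,
      df = unname(tt$parameter), group_means = gm,
      significant = tt$p.value < 0.05),
      class = "group_comparison"))
  }
  if (!"timepoint" %in% names(records))
    stop("two-way design needs a `timepoint` column", call. = FALSE)
  tps <- unique(records$timepoint)
  for (g in groups) for (tp in tps)
    check_cell(records$group == g & records$timepoint == tp,
               paste(g, tp, sep = ":"))
  fit <- stats::aov(records[[measure]] ~ factor(records$group) *
                      factor(records$timepoint))
  tab <- summary(fit)[[1]]
  rownames(tab) <- c("group", "timepoint", "group:timepoint", "residuals")
  contrasts <- list()
  for (g in groups) {
    sel <- records$group == g
    if (length(tps) == 2L) {
      tt <- stats::t.test(records[[measure]][sel & records$timepoint == tps[1]],
                          records[[measure]][sel & records$timepoint == tps[2]],
                          var.equal = TRUE)
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        contrast = sprintf("%s: %s vs %s", g, tps[1], tps[2]),
        statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  }
  for (tp in tps) {
    sel <- records$timepoint == tp
    tt <- stats::t.test(records[[measure]][sel & records$group == groups[1]],
                        records[[measure]][sel & records$group == groups[2]],
                        var.equal = TRUE)
    contrasts[[length(contrasts) + 1L]] <- data.frame(
      contrast = sprintf("%s: %s vs %s", tp, groups[1], groups[2]),
      statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  structure(list(
    design = design, measure = measure,
    anova_table = tab,
    p_group = tab["group", "Pr(>F)"],
    p_interaction = tab["group:timepoint", "Pr(>F)"],
    contrasts = do.call(rbind, contrasts)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> measure: %s, design: %s\n",
              x$measure, x$design))
  if (x$design == "two_sample") {
    cat(sprintf("  t = %.3f, df = %g, p = %.4g%s\n", x$statistic, x$df,
                x$p_value, if (x$p_value < 0.05) " *" else ""))
  } else {
    cat(sprintf("  ANOVA p(group) = %.4g, p(interaction) = %.4g\n",
                x$p_group, x$p_interaction))
  }
  invisible(x)
}

#' Pearson correlation between paired per-animal measures
#'
#' @param x,y paired numeric vectors, complete, length >= 3, each with
#'   nonzero variance.
#' @return a list with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  if (any(!keep)) stop("`x` and `y` must be complete", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in `x` or `y`", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
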