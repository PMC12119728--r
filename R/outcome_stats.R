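# Outcome statistics: per-variable cohort comparisons (rank-sum),
# Kaplan-Meier survival dichotomised on an imaging marker, and the tissue
# metabolomics screen (Welch t / FDR q / PCA).

#' Per-variable two-group comparison (rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test per numeric variable between two
#' independent cohorts, reported with per-group mean +/- SD in a
#' table-style layout.
#'
#' @param df data.frame of per-lesion variables.
#' @param group two-level factor/vector, one entry per row.
#' @param variables columns to compare; default all numeric columns.
#' @return data.frame: variable, mean/sd per group, p_value, test.
#' @export
compare_groups <- function(df, group, variables = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(table(group) < 2L)) stop("each group needs >= 2 observations")
  if (is.null(variables))
    variables <- names(df)[vapply(df, is.numeric, logical(1L))]
  g1 <- levels(group)[1L]; g2 <- levels(group)[2L]
  rows <- lapply(variables, function(v) {
    a <- df[[v]][group == g1]; b <- df[[v]][group == g2]
    # exact rank-sum when sample sizes permit and there are no ties
    p <- suppressWarnings(wilcox.test(a, b)$p.value)
    data.frame(variable = v, mean_1 = mean(a), sd_1 = sd(a),
               mean_2 = mean(b), sd_2 = sd(b), p_value = p,
               test = "wilcoxon-rank-sum")
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", g1), paste0("sd_", g1),
                       paste0("mean_", g2), paste0("sd_", g2))
  out
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with right censoring (thin wrapper over the
#' survival package, returned as a plain step-function table).
#'
#' @param time_months nonnegative times.
#' @param event 1 = event, 0 = censored.
#' @return list: curve (data.frame time, surv, n_risk, n_event), median
#'   (NA with \code{median_defined = FALSE} when the curve never reaches
#'   0.5).
#' @export
km_estimate <- function(time_months, event) {
  if (any(time_months < 0)) stop("times must be >= 0")
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1)
  med <- unname(summary(sf)$table["median"])
  list(curve = data.frame(time = sf$time, surv = sf$surv,
                          n_risk = sf$n.risk, n_event = sf$n.event),
       median = med, median_defined = is.finite(med))
}

#' Dichotomise survival on a marker and compare the two groups
#'
#' Records with \code{marker >= cutoff} form the high group. Kaplan-Meier
#' curves and medians are computed per group; the groups are compared both
#' by a two-tailed Mann-Whitney test on the observed survival times (the
#' comparison used alongside the marker cutoff in the source analyses —
#' unusual under censoring, so the conventional log-rank test is always
#' reported as well).
#'
#' @param records data.frame with time and event columns.
#' @param marker numeric marker per record (e.g. SUVmax).
#' @param cutoff dichotomisation threshold.
#' @param time_col,event_col column names.
#' @return a \code{survival_split}: per-group KM output, medians,
#'   p_mann_whitney, p_logrank, n per group.
#' @export
dichotomise_survival <- function(records, marker, cutoff,
                                 time_col = "time_months",
                                 event_col = "event") {
  tt <- records[[time_col]]; ev <- records[[event_col]]
  high <- marker >= cutoff
  if (!any(high) || !all(high))
    if (sum(high) == 0L || sum(!high) == 0L)
      stop(sprintf("cutoff %g leaves an empty group", cutoff))
  km_low <- km_estimate(tt[!high], ev[!high])
  km_high <- km_estimate(tt[high], ev[high])
  p_mw <- suppressWarnings(wilcox.test(tt[high], tt[!high],
                                       exact = FALSE)$p.value)
  grp <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ grp)
  p_lr <- 1 - stats::pchisq(sd_$chisq, df = 1)
  structure(list(km_low = km_low, km_high = km_high,
                 median_low = km_low$median, median_high = km_high$median,
                 p_mann_whitney = p_mw, p_logrank = p_lr,
                 cutoff = cutoff, n_low = sum(!high), n_high = sum(high)),
            class = "survival_split")
}

#' @export
print.survival_split <- function(x, ...) {
  cat(sprintf(
    "<survival_split> cutoff %g: n = %d low / %d high\n  median %s v %s months; Mann-Whitney p = %.4g, log-rank p = %.4g\n",
    x$cutoff, x$n_low, x$n_high,
    if (x$km_low$median_defined) sprintf("%.3g", x$median_low) else "NA",
    if (x$km_high$median_defined) sprintf("%.3g", x$median_high) else "NA",
    x$p_mann_whitney, x$p_logrank))
  invisible(x)
}

#' Metabolite screen: Welch t-tests, FDR q-values, fold-changes
#'
#' Per metabolite and group pair: Welch's unequal-variance t-test on
#' (optionally log-transformed) abundances, Benjamini-Hochberg q-values
#' across metabolites within the pair, fold-change as the ratio of group
#' geometric means, and a shading category — significant at p <= 0.05,
#' trend at 0.05 < p < 0.10, direction by the fold-change.
#'
#' @param mat metabolites x samples abundance matrix (already normalised
#'   to tissue mass).
#' @param groups factor per sample (column).
#' @param pairs list of length-2 character vectors of group levels;
#'   default all pairwise.
#' @param log_transform log the abundances before testing (default TRUE).
#' @return data.frame: metabolite, group_a, group_b, fold_change, t, df,
#'   p, q, category.
#' @export
metabolite_screen <- function(mat, groups, pairs = NULL,
                              log_transform = TRUE) {
  groups <- factor(groups)
  if (ncol(mat) != length(groups)) stop("one group label per column needed")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 samples")
  if (is.null(pairs)) {
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2L, simplify = FALSE)
  }
  lmat <- if (log_transform) log(mat) else mat
  out <- lapply(pairs, function(pr) {
    ia <- which(groups == pr[1L]); ib <- which(groups == pr[2L])
    res <- t(apply(lmat, 1L, function(v) {
      a <- v[ia]; b <- v[ib]
      if (var(a) == 0 && var(b) == 0)
        return(c(NA_real_, NA_real_, NA_real_))
      tt <- t.test(b, a, var.equal = FALSE)
      c(unname(tt$statistic), unname(tt$parameter), tt$p.value)
    }))
    # geometric-mean ratio, computed on the log scale regardless of the
    # transform used for testing
    fc <- exp(rowMeans(log(mat[, ib, drop = FALSE])) -
                rowMeans(log(mat[, ia, drop = FALSE])))
    q <- p.adjust(res[, 3L], method = "BH")
    cat_ <- ifelse(is.na(res[, 3L]), "ns",
            ifelse(res[, 3L] <= 0.05, ifelse(fc > 1, "sig-up", "sig-down"),
            ifelse(res[, 3L] < 0.10, ifelse(fc > 1, "trend-up",
                                            "trend-down"), "ns")))
    data.frame(metabolite = rownames(mat), group_a = pr[1L],
               group_b = pr[2L], fold_change = fc, t = res[, 1L],
               df = res[, 2L], p = res[, 3L], q = q, category = cat_,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' PCA overview of a metabolite matrix
#'
#' Principal components of the (log) abundance matrix with samples as
#' observations; reports scores and the percent variance of the leading
#' components.
#'
#' @param mat metabolites x samples matrix.
#' @param n_components leading components to report (default 3).
#' @param log_transform,scale. preprocessing switches.
#' @return list: scores (samples x components), percent_variance (all
#'   components; nonnegative, non-increasing, sums to 100).
#' @export
pca_overview <- function(mat, n_components = 3, log_transform = TRUE,
                         scale. = FALSE) {
  if (ncol(mat) < 2L) stop("need >= 2 samples")
  x <- t(if (log_transform) log(mat) else mat)
  keep <- apply(x, 2L, var) > 0 | !scale.
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  pv <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE], percent_variance = pv)
}
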