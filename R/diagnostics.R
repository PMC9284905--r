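# Diagnostic evaluation: confusion metrics, ROC and precision-recall curves,
# optimal cut-points, paired AUC comparison, joint two-threshold grids.

#' Threshold-specific diagnostic metrics from confusion counts
#'
#' Computes sensitivity, specificity, predictive values, accuracy, the F1
#' score (harmonic mean of sensitivity and PPV) and the Youden index
#' `J = sensitivity + specificity - 1`. Each metric is returned both as a
#' fraction and as the integer percent used in clinical tables (rounded half
#' away from zero). Ratios with a zero denominator are undefined and returned
#' as `NA`, never silently as zero.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, the fractional metrics
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `f1`,
#'   `youden_j`, and integer-percent columns `sensitivity_pct` ...
#'   `f1_pct`.
#' @examples
#' confusion_metrics(tp = 41, fp = 21, tn = 16, fn = 4)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("confusion counts must be non-negative integers.",
                "vatmets_domain_error")
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp)
  npv <- ratio(tn, tn + fn)
  acc <- ratio(tp + tn, tp + fp + tn + fn)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (sens + ppv) > 0) {
    2 * sens * ppv / (sens + ppv)
  } else {
    NA_real_
  }
  out <- tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    accuracy = acc, f1 = f1,
    youden_j = sens + spec - 1
  )
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy", "f1")) {
    out[[paste0(m, "_pct")]] <- as_percent(out[[m]])
  }
  out
}

check_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0, 1))) {
    stop_domain("labels must be logical or 0/1.", "vatmets_domain_error")
  }
  as.integer(labels)
}

# counts at every candidate threshold (positivity: score >= threshold),
# via cumulative sums over the descending score order
threshold_counts <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- c(which(diff(s) != 0), length(s)) # last index of each unique value
  tp <- cumsum(l)[last]
  fp <- cumsum(1 - l)[last]
  tibble(
    threshold = s[last], tp = tp, fp = fp,
    fn = n_pos - tp, tn = n_neg - fp,
    sensitivity = tp / n_pos, specificity = tn / n_neg,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  )
}

# DeLong placement values via midranks: for each positive, the fraction of
# negatives it outranks (ties count one half), and symmetrically
placements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Receiver operating characteristic analysis
#'
#' Builds the ROC curve of a continuous marker against a binary outcome, with
#' candidate cut-points at the unique observed marker values and positivity
#' defined as marker `>=` cut-point. Reports the trapezoidal AUC with a 95%
#' Wald confidence interval from the nonparametric placement-value
#' (DeLong) variance estimator, the cut-point maximizing the Youden index and
#' the cut-point maximizing the sensitivity-specificity product (ties broken
#' towards the lowest threshold, favouring sensitivity in a screening
#' setting), and full threshold metrics at each.
#'
#' @param data Data frame.
#' @param truth Unquoted column: binary outcome (logical or 0/1).
#' @param score Unquoted column: marker values. Rows with a missing marker or
#'   outcome are dropped (complete-case).
#' @param conf_level Confidence level for the AUC interval.
#' @return Object of class `roc_result`; see [tidy()] / [glance()] methods.
#' @examples
#' d <- tibble::tibble(y = c(0, 0, 1, 1), x = c(1, 2, 3, 4))
#' r <- roc_curve(d, y, x)
#' glance(r)
#' @export
roc_curve <- function(data, truth, score, conf_level = 0.95) {
  labels <- check_labels(dplyr::pull(data, {{ truth }}))
  scores <- dplyr::pull(data, {{ score }})
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]
  scores <- scores[keep]
  if (length(unique(labels)) < 2) {
    stop_domain("both outcome classes must be present.", "vatmets_domain_error")
  }
  counts <- threshold_counts(scores, labels)
  pts <- tibble(
    threshold = c(Inf, counts$threshold),
    fpr = c(0, 1 - counts$specificity),
    sensitivity = c(0, counts$sensitivity),
    specificity = c(1, counts$specificity)
  )
  auc <- trapezoid_area(pts$fpr, pts$sensitivity)
  pl <- placements(scores, labels)
  var_auc <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * zq * sqrt(var_auc)))

  # ties (up to float noise) break towards the lowest threshold
  j <- counts$sensitivity + counts$specificity - 1
  best_j <- which(j >= max(j) - 1e-9)
  best_j <- best_j[which.min(counts$threshold[best_j])]
  prod_crit <- counts$sensitivity * counts$specificity
  best_p <- which(prod_crit >= max(prod_crit) - 1e-9)
  best_p <- best_p[which.min(counts$threshold[best_p])]
  metrics_at <- function(i) {
    dplyr::bind_cols(
      tibble(cutpoint = counts$threshold[[i]]),
      confusion_metrics(counts$tp[[i]], counts$fp[[i]],
                        counts$tn[[i]], counts$fn[[i]])
    )
  }
  structure(
    list(
      points = pts,
      auc = auc,
      auc_var = var_auc,
      ci_low = ci[[1]], ci_high = ci[[2]],
      conf_level = conf_level,
      youden = metrics_at(best_j),
      product = metrics_at(best_p),
      n_pos = sum(labels == 1), n_neg = sum(labels == 0),
      scores = scores, labels = labels
    ),
    class = "roc_result"
  )
}

trapezoid_area <- function(x, y) {
  o <- order(x, y)
  x <- x[o]
  y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.0f%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  cat(sprintf("  Youden cut-point %.4g (sens %d%%, spec %d%%)\n",
              x$youden$cutpoint, x$youden$sensitivity_pct,
              x$youden$specificity_pct))
  invisible(x)
}

#' Paired comparison of two correlated AUCs
#'
#' DeLong's nonparametric test for the difference between the AUCs of two
#' markers measured on the same subjects: the variance of the difference is
#' estimated from the covariance of the placement values, and a two-sided
#' normal p-value is reported. Identical scores give a degenerate zero
#' variance; the difference is then exactly zero and `p = 1` with
#' `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Marker values on the same subjects.
#' @param labels Binary outcome (logical or 0/1).
#' @return One-row tibble: `auc_a`, `auc_b`, `delta_auc`, `z`, `p_value`,
#'   `degenerate`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop_domain("scores and labels must have equal length.",
                "vatmets_domain_error")
  }
  labels <- check_labels(labels)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[keep]
  scores_b <- scores_b[keep]
  labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    stop_domain("both outcome classes must be present.", "vatmets_domain_error")
  }
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  var_delta <- var(pa$v10 - pb$v10) / m + var(pa$v01 - pb$v01) / n
  delta <- pa$auc - pb$auc
  if (var_delta < 1e-12) {
    return(tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
                  z = 0, p_value = 1, degenerate = TRUE))
  }
  z <- delta / sqrt(var_delta)
  tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, z = z,
         p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Precision-recall analysis
#'
#' Precision (PPV) against recall (sensitivity) over the same `>=`-threshold
#' convention as [roc_curve()]. The curve is anchored at recall zero with the
#' precision of the most stringent threshold, and the area is the trapezoidal
#' integral over recall (0-1 scale; the no-skill baseline equals the outcome
#' prevalence).
#'
#' @inheritParams roc_curve
#' @return Object of class `pr_result` with `points` (threshold, recall,
#'   precision) and `pr_area`.
#' @export
pr_curve <- function(data, truth, score) {
  labels <- check_labels(dplyr::pull(data, {{ truth }}))
  scores <- dplyr::pull(data, {{ score }})
  keep <- !is.na(labels) & !is.na(scores)
  labels <- labels[keep]
  scores <- scores[keep]
  if (sum(labels == 1) == 0) {
    stop_domain("no positive cases: precision-recall undefined.",
                "vatmets_domain_error")
  }
  counts <- threshold_counts(scores, labels)
  pts <- tibble(
    threshold = c(Inf, counts$threshold),
    recall = c(0, counts$sensitivity),
    precision = c(counts$precision[[1]], counts$precision)
  )
  # integrate in threshold order (recall is nondecreasing along it);
  # sorting would mis-pair precisions across equal-recall plateaus
  area <- sum(diff(pts$recall) *
                (head(pts$precision, -1) + tail(pts$precision, -1)) / 2)
  structure(list(points = pts, pr_area = area,
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0)),
            class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf("<pr_result> area %.3f over %d thresholds (%d pos / %d neg)\n",
              x$pr_area, nrow(x$points) - 1, x$n_pos, x$n_neg))
  invisible(x)
}

#' Joint two-threshold accuracy grid search
#'
#' Evaluates the rule "positive if marker 1 >= t1 AND marker 2 >= t2" over a
#' grid of threshold pairs, as used to combine waist circumference with a
#' second adiposity marker. Rows missing either marker are excluded
#' (complete-case). The returned accuracy matrix supports contour plotting;
#' the best pair maximizes accuracy, with ties broken by higher F1 and then
#' by lower thresholds.
#'
#' @param data Data frame.
#' @param truth Unquoted binary outcome column.
#' @param marker1,marker2 Unquoted marker columns.
#' @param grid1,grid2 Numeric threshold grids; default to the unique observed
#'   marker values, or to a regular grid at `step1`/`step2` spanning the
#'   observed range when a step is given.
#' @param step1,step2 Optional grid resolutions (e.g. 0.5 cm for waist, 1 g
#'   for fat mass).
#' @return Object of class `grid_search_result`: `grid1`, `grid2`,
#'   `accuracy` matrix, `best` (one-row tibble with both thresholds and full
#'   [confusion_metrics()]), marker names, and counts.
#' @export
joint_threshold_grid <- function(data, truth, marker1, marker2,
                                 grid1 = NULL, grid2 = NULL,
                                 step1 = NULL, step2 = NULL) {
  labels <- check_labels(dplyr::pull(data, {{ truth }}))
  x1 <- dplyr::pull(data, {{ marker1 }})
  x2 <- dplyr::pull(data, {{ marker2 }})
  keep <- !is.na(x1) & !is.na(x2) & !is.na(labels)
  x1 <- x1[keep]
  x2 <- x2[keep]
  labels <- labels[keep]
  if (length(labels) == 0) {
    stop_domain("no complete cases for the marker pair.",
                "vatmets_missing_error")
  }
  make_grid <- function(x, grid, step) {
    if (!is.null(grid)) return(sort(unique(grid)))
    if (is.null(step)) return(sort(unique(x)))
    seq(floor(min(x) / step) * step, ceiling(max(x) / step) * step, by = step)
  }
  grid1 <- make_grid(x1, grid1, step1)
  grid2 <- make_grid(x2, grid2, step2)
  p1 <- outer(x1, grid1, ">=")
  p2 <- outer(x2, grid2, ">=")
  pos <- labels == 1
  tp <- crossprod(p1[pos, , drop = FALSE], p2[pos, , drop = FALSE])
  fp <- crossprod(p1[!pos, , drop = FALSE], p2[!pos, , drop = FALSE])
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  n <- n_pos + n_neg
  fn <- n_pos - tp
  tn <- n_neg - fp
  acc <- (tp + tn) / n
  # argmax with ties -> higher F1, then lower thresholds (t1 first)
  cand <- which(acc == max(acc), arr.ind = TRUE)
  if (nrow(cand) > 1) {
    f1 <- apply(cand, 1, function(ij) {
      s <- tp[ij[1], ij[2]] / n_pos
      den <- tp[ij[1], ij[2]] + fp[ij[1], ij[2]]
      p <- if (den > 0) tp[ij[1], ij[2]] / den else NA_real_
      if (is.na(p) || (s + p) == 0) -Inf else 2 * s * p / (s + p)
    })
    cand <- cand[f1 == max(f1), , drop = FALSE]
    o <- order(grid1[cand[, 1]], grid2[cand[, 2]])
    cand <- cand[o[1], , drop = FALSE]
  }
  i <- cand[1, 1]
  j <- cand[1, 2]
  best <- dplyr::bind_cols(
    tibble(threshold1 = grid1[[i]], threshold2 = grid2[[j]]),
    confusion_metrics(tp[i, j], fp[i, j], tn[i, j], fn[i, j])
  )
  structure(
    list(
      grid1 = grid1, grid2 = grid2, accuracy = acc, best = best,
      marker1 = as_name(enquo(marker1)), marker2 = as_name(enquo(marker2)),
      n_pos = n_pos, n_neg = n_neg
    ),
    class = "grid_search_result"
  )
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "<grid_search_result> %s x %s (%d x %d grid): best accuracy %d%% at (%.4g, %.4g)\n",
    x$marker1, x$marker2, length(x$grid1), length(x$grid2),
    x$best$accuracy_pct, x$best$threshold1, x$best$threshold2
  ))
  invisible(x)
}
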