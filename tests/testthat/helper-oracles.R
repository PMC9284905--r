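# Independent oracles used across the test files. These deliberately avoid the
# package's own code paths: brute-force pair counting, exhaustive threshold
# scans and explicit refits.

# AUC as the concordant-pair fraction (ties count one half)
oracle_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  mean(cmp)
}

# exhaustive scan over observed thresholds for a cut-point criterion;
# ties broken towards the lowest threshold
oracle_cutpoint <- function(scores, labels, criterion = c("youden", "product")) {
  criterion <- match.arg(criterion)
  thr <- sort(unique(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  val <- vapply(thr, function(t) {
    sens <- sum(scores >= t & labels == 1) / n_pos
    spec <- sum(scores < t & labels == 0) / n_neg
    if (criterion == "youden") sens + spec - 1 else sens * spec
  }, numeric(1))
  best <- which(abs(val - max(val)) < 1e-12)
  list(threshold = min(thr[best]), value = max(val))
}

# exhaustive double loop for the joint two-threshold rule
oracle_joint_accuracy <- function(x1, x2, labels, grid1, grid2) {
  best <- -Inf
  for (t1 in grid1) {
    for (t2 in grid2) {
      pred <- x1 >= t1 & x2 >= t2
      best <- max(best, mean(pred == (labels == 1)))
    }
  }
  best
}

# precision-recall area by explicit threshold enumeration (threshold order)
oracle_pr_area <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  rec <- 0
  prec_first <- sum(scores >= thr[1] & labels == 1) / sum(scores >= thr[1])
  prec <- prec_first
  area <- 0
  for (t in thr) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    r <- tp / n_pos
    p <- tp / (tp + fp)
    area <- area + (r - rec) * (p + prec) / 2
    rec <- r
    prec <- p
  }
  area
}

# build a strip-profile tibble directly (for boundary-detection unit tests)
make_strips <- function(total, pct_fm, pixel_width = 0.48) {
  n <- length(total)
  fat <- ifelse(total > 0, total * pct_fm / 100, 0)
  tibble::tibble(
    strip = seq_len(n),
    x_left = (seq_len(n) - 1) * pixel_width,
    x_right = seq_len(n) * pixel_width,
    fat = fat,
    lean = total - fat,
    bone = 0,
    total_mass = total,
    pct_fm = ifelse(total > 0, pct_fm, NA_real_),
    is_air = total <= 0
  )
}

# analytic tissue masses of an elliptical phantom (independent re-derivation)
oracle_phantom_truth <- function(width, sagittal, t, fs, fv,
                                 fat_density = 0.90, lean_density = 1.05) {
  a <- width / 2
  b <- sagittal / 2
  area_outer <- pi * a * b
  area_inner <- pi * (a - t) * (b - t)
  annulus <- area_outer - area_inner
  list(
    sfm = fs * fat_density * annulus,
    vfm = fv * fat_density * area_inner,
    lean = lean_density * ((1 - fs) * annulus + (1 - fv) * area_inner),
    area = area_outer
  )
}
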