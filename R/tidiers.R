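# broom-style tidy()/glance() methods for the package's result objects.

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(
    auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    conf_level = x$conf_level,
    cutpoint_youden = x$youden$cutpoint,
    youden_j = x$youden$youden_j,
    cutpoint_product = x$product$cutpoint,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @method tidy pr_result
#' @export
tidy.pr_result <- function(x, ...) x$points

#' @method glance pr_result
#' @export
glance.pr_result <- function(x, ...) {
  tibble(pr_area = x$pr_area, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @method tidy grid_search_result
#' @export
tidy.grid_search_result <- function(x, ...) {
  long <- expand.grid(threshold1 = x$grid1, threshold2 = x$grid2,
                      KEEP.OUT.ATTRS = FALSE)
  long$accuracy <- as.vector(x$accuracy)
  out <- as_tibble(long)
  names(out)[1:2] <- c(x$marker1, x$marker2)
  out
}

#' @method glance grid_search_result
#' @export
glance.grid_search_result <- function(x, ...) {
  dplyr::bind_cols(tibble(marker1 = x$marker1, marker2 = x$marker2), x$best)
}

#' @method tidy association_result
#' @export
tidy.association_result <- function(x, ...) x$terms

#' @method glance association_result
#' @export
glance.association_result <- function(x, ...) {
  tibble(outcome = x$outcome, r2 = x$r2, n = x$n,
         log10_outcome = x$log10_outcome)
}

#' @method tidy vfm_model
#' @export
tidy.vfm_model <- function(x, ...) {
  ct <- summary(x$fit)$coefficients
  tibble(
    term = rownames(ct),
    estimate = unname(ct[, "Estimate"]),
    std_error = unname(ct[, "Std. Error"]),
    statistic = unname(ct[, "t value"]),
    p_value = unname(ct[, "Pr(>|t|)"])
  )
}

#' @method glance vfm_model
#' @export
glance.vfm_model <- function(x, ...) {
  tibble(r2 = x$r2, see = x$see, press = x$press, sse = x$sse, n = x$n,
         n_selected = length(x$selected))
}
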