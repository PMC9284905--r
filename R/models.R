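# Standardized association models and the anthropometric VFM prediction model
# (stepwise selection, leave-one-out cross-validation, PRESS).

#' Standardized adjusted regression of a risk factor on fat variables
#'
#' Ordinary least squares of a (optionally log10-transformed) outcome on
#' z-scored predictors, with covariates entered unstandardized, so the
#' coefficients of the predictors are standardized effect sizes directly
#' comparable across fat variables. The outcome is z-scored after any log
#' transform. Reports two-sided coefficient p-values, the model R^2 and
#' variance inflation factors (diagonal of the inverse correlation matrix of
#' the model terms).
#'
#' @param data Data frame.
#' @param outcome Column name of the outcome (character).
#' @param predictors Character vector of predictor columns (standardized).
#' @param covariates Character vector of adjustment columns (unstandardized;
#'   character/factor columns such as sex are expanded via contrasts).
#' @param log10_outcome Log10-transform the outcome first (for positively
#'   skewed variables such as triglycerides and insulin).
#' @return Object of class `association_result`; `tidy()` gives one row per
#'   predictor (`term`, `std_beta`, `p_value`, `vif`), `glance()` the model
#'   `r2`, `n` and outcome name.
#' @export
standardized_regression <- function(data, outcome, predictors,
                                    covariates = character(),
                                    log10_outcome = FALSE) {
  cols <- c(outcome, predictors, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop_domain(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
                "vatmets_missing_error")
  }
  d <- as_tibble(data)[cols]
  d <- d[complete.cases(d), ]
  n <- nrow(d)
  if (n < length(predictors) + length(covariates) + 2) {
    stop_domain("too few complete cases for the requested model.",
                "vatmets_domain_error")
  }
  y <- d[[outcome]]
  if (log10_outcome) {
    check_positive(y, outcome)
    y <- log10(y)
  }
  zscore <- function(x) (x - mean(x)) / sd(x)
  d$.y <- zscore(y)
  for (p in predictors) d[[p]] <- zscore(d[[p]])
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  fit <- lm(stats::as.formula(paste(".y ~", rhs)), data = d)
  X <- model.matrix(fit)[, -1, drop = FALSE]
  if (qr(X)$rank < ncol(X)) {
    ali <- stats::alias(fit)$Complete
    bad <- if (is.null(ali)) "unknown" else paste(rownames(ali), collapse = ", ")
    stop_domain(paste0("rank-deficient model; collinear terms: ", bad),
                "vatmets_collinearity_error")
  }
  vif <- if (ncol(X) > 1) diag(solve(cor(X))) else setNames(1, colnames(X))
  sm <- summary(fit)
  ct <- sm$coefficients
  res <- tibble(
    term = predictors,
    std_beta = unname(ct[predictors, "Estimate"]),
    p_value = unname(ct[predictors, "Pr(>|t|)"]),
    vif = unname(vif[predictors])
  )
  structure(
    list(terms = res, r2 = sm$r.squared, n = n, outcome = outcome,
         log10_outcome = log10_outcome, fit = fit),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association_result> %s%s ~ %s (n = %d, R2 = %.3f)\n",
              if (x$log10_outcome) "log10 " else "", x$outcome,
              paste(x$terms$term, collapse = " + "), x$n, x$r2))
  print(x$terms)
  invisible(x)
}

# one forward/backward stepwise pass; returns the updated selection
step_p_once <- function(d, outcome, selected, candidates, entry_p, removal_p) {
  fit_with <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    lm(stats::as.formula(paste(outcome, "~", rhs)), data = d)
  }
  # forward: add the most significant remaining candidate if p < entry_p
  remaining <- setdiff(candidates, selected)
  if (length(remaining)) {
    pvals <- vapply(remaining, function(cand) {
      fit <- fit_with(c(selected, cand))
      ct <- summary(fit)$coefficients
      if (cand %in% rownames(ct)) ct[cand, "Pr(>|t|)"] else NA_real_
    }, numeric(1))
    pvals[is.na(pvals)] <- Inf
    if (min(pvals) < entry_p) {
      selected <- c(selected, remaining[[which.min(pvals)]])
    }
  }
  # backward: drop the least significant included term while p >= removal_p
  repeat {
    if (!length(selected)) break
    ct <- summary(fit_with(selected))$coefficients
    p_in <- ct[selected, "Pr(>|t|)"]
    p_in[is.na(p_in)] <- 0 # perfect fit: coefficients exact, keep them
    if (max(p_in) >= removal_p) {
      selected <- setdiff(selected, selected[[which.max(p_in)]])
    } else {
      break
    }
  }
  selected
}

#' Fit the anthropometric VFM prediction model
#'
#' Stepwise (forward-backward, p-value based: entry p < 0.05, removal
#' p >= 0.10) linear regression of measured visceral fat mass on candidate
#' anthropometric predictors, fit per sex. Leave-one-out cross-validation
#' residuals come from the closed-form leverage identity
#' `e_i / (1 - h_ii)`, and PRESS is their sum of squares (never smaller than
#' the in-sample residual sum of squares).
#'
#' @param data Data frame containing the outcome and candidates.
#' @param sex Optional `"male"`/`"female"` filter applied to a `sex` column.
#' @param candidates Character vector of candidate predictors; defaults to
#'   the standard anthropometric set (waist, weight, height, waist:height,
#'   conicity, BMI, hip, waist:hip, body adiposity index, age).
#' @param outcome Outcome column (grams), default `"vfm_measured"`.
#' @param entry_p,removal_p Stepwise thresholds.
#' @return Object of class `vfm_model`: the `lm` fit, `selected` predictors,
#'   `r2`, `see` (residual SD, g), `press` (g^2), `loocv_residuals`, `n`.
#' @export
fit_vfm_model <- function(data, sex = NULL,
                          candidates = c("wc", "weight", "height", "whtr",
                                         "conicity", "bmi", "hip", "whr",
                                         "bai", "age"),
                          outcome = "vfm_measured",
                          entry_p = 0.05, removal_p = 0.10) {
  d <- as_tibble(data)
  if (!is.null(sex)) {
    d <- d[check_sex(d$sex) == check_sex(sex), ]
  }
  cols <- c(outcome, candidates)
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols)) {
    stop_domain(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
                "vatmets_missing_error")
  }
  d <- d[cols]
  d <- d[complete.cases(d), ]
  if (nrow(d) <= length(candidates) + 5) {
    stop_domain("too few complete cases for stepwise selection.",
                "vatmets_domain_error")
  }
  selected <- character()
  for (iter in seq_len(50)) {
    updated <- step_p_once(d, outcome, selected, candidates, entry_p, removal_p)
    if (identical(updated, selected)) break
    selected <- updated
  }
  if (!length(selected)) {
    warn("no candidate predictor met the entry criterion; intercept-only model.")
  }
  rhs <- if (length(selected)) paste(selected, collapse = " + ") else "1"
  fit <- lm(stats::as.formula(paste(outcome, "~", rhs)), data = d)
  e <- resid(fit)
  h <- hatvalues(fit)
  loo <- e / (1 - h)
  sm <- summary(fit)
  structure(
    list(fit = fit, selected = selected,
         coefficients = coef(fit),
         r2 = sm$r.squared, see = sm$sigma,
         press = sum(loo^2), sse = sum(e^2),
         loocv_residuals = unname(loo), n = nrow(d), outcome = outcome),
    class = "vfm_model"
  )
}

#' @export
print.vfm_model <- function(x, ...) {
  cat(sprintf("<vfm_model> %s ~ %s\n", x$outcome,
              if (length(x$selected)) paste(x$selected, collapse = " + ") else "1"))
  cat(sprintf("  n = %d, R2 = %.3f, SEE = %.1f g, PRESS = %.0f g^2\n",
              x$n, x$r2, x$see, x$press))
  invisible(x)
}
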