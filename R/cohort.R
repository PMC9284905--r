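# Correlated synthetic cohorts with sex-stratified marginals emulating an
# adult Asian Indian study population.

cohort_vars <- c("age", "height", "wc", "bmi", "whr", "sft", "sd_anthro",
                 "tg", "hdl", "glucose", "sbp", "dbp", "insulin")

#' Default per-sex marginal distributions
#'
#' Means and SDs of the simulated measurements, per sex. Gaussian variables
#' carry `mean`/`sd` on the measurement scale; log-normal ones (triglycerides,
#' insulin -- both positively skewed in adult cohorts) carry `meanlog`/`sdlog`
#' in the same columns. Values are realistic for migrant Asian Indian adults:
#' a population with modest BMI but centrally distributed fat, frequent
#' dyslipidemia and raised fasting glucose.
#'
#' @return Named list (`male`, `female`) of tibbles with columns
#'   `var`, `mean`, `sd`, `dist`.
#' @export
default_marginals <- function() {
  male <- tibble(
    var = cohort_vars,
    mean = c(45.1, 1.70, 92.8, 25.4, 0.94, 28.6, 22.2,
             log(1.80), 1.09, 5.35, 123.0, 78.0, log(75)),
    sd = c(13.0, 0.060, 10.0, 3.7, 0.060, 12.5, 2.2,
           0.60, 0.30, 0.50, 18.5, 8.9, 0.45),
    dist = c(rep("normal", 7), "lognormal", rep("normal", 4), "lognormal")
  )
  female <- tibble(
    var = cohort_vars,
    mean = c(43.5, 1.56, 85.7, 26.3, 0.84, 30.7, 21.3,
             log(1.20), 1.30, 5.18, 114.2, 72.5, log(72)),
    sd = c(13.2, 0.060, 10.0, 4.7, 0.075, 10.9, 2.8,
           0.50, 0.33, 0.51, 20.2, 9.1, 0.45),
    dist = c(rep("normal", 7), "lognormal", rep("normal", 4), "lognormal")
  )
  list(male = male, female = female)
}

#' Default latent correlation structure
#'
#' Correlations among the latent Gaussian scores from which all measurements
#' are mapped. Anthropometric measures of abdominal size correlate strongly
#' with each other, moderately with the metabolic risk factors (which cluster
#' with one another -- the phenomenon the package's diagnostics quantify),
#' and weakly with age; height is nearly independent of the rest. Values are
#' plausible field magnitudes chosen for the simulator, not estimates from
#' any particular dataset.
#'
#' @return A symmetric positive-definite correlation matrix over
#'   `r length(cohort_vars)` variables.
#' @export
default_correlation <- function() {
  v <- cohort_vars
  k <- length(v)
  R <- diag(k)
  dimnames(R) <- list(v, v)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("age", "height", -0.10)
  set_r("age", "wc", 0.25); set_r("age", "bmi", 0.15)
  set_r("age", "whr", 0.25); set_r("age", "sft", 0.05)
  set_r("age", "sd_anthro", 0.25)
  set_r("age", "tg", 0.15); set_r("age", "hdl", -0.05)
  set_r("age", "glucose", 0.30); set_r("age", "sbp", 0.35)
  set_r("age", "dbp", 0.25); set_r("age", "insulin", 0.05)
  set_r("height", "wc", 0.05); set_r("height", "sbp", 0.05)
  set_r("wc", "bmi", 0.85); set_r("wc", "whr", 0.60)
  set_r("wc", "sft", 0.60); set_r("wc", "sd_anthro", 0.80)
  set_r("wc", "tg", 0.30); set_r("wc", "hdl", -0.30)
  set_r("wc", "glucose", 0.20); set_r("wc", "sbp", 0.25)
  set_r("wc", "dbp", 0.30); set_r("wc", "insulin", 0.45)
  set_r("bmi", "whr", 0.35); set_r("bmi", "sft", 0.65)
  set_r("bmi", "sd_anthro", 0.70)
  set_r("bmi", "tg", 0.25); set_r("bmi", "hdl", -0.25)
  set_r("bmi", "glucose", 0.15); set_r("bmi", "sbp", 0.25)
  set_r("bmi", "dbp", 0.30); set_r("bmi", "insulin", 0.45)
  set_r("whr", "sft", 0.30); set_r("whr", "sd_anthro", 0.50)
  set_r("whr", "tg", 0.25); set_r("whr", "hdl", -0.20)
  set_r("whr", "glucose", 0.15); set_r("whr", "sbp", 0.15)
  set_r("whr", "dbp", 0.20); set_r("whr", "insulin", 0.25)
  set_r("sft", "sd_anthro", 0.50)
  set_r("sft", "tg", 0.20); set_r("sft", "hdl", -0.20)
  set_r("sft", "glucose", 0.10); set_r("sft", "sbp", 0.15)
  set_r("sft", "dbp", 0.20); set_r("sft", "insulin", 0.35)
  set_r("sd_anthro", "tg", 0.30); set_r("sd_anthro", "hdl", -0.25)
  set_r("sd_anthro", "glucose", 0.20); set_r("sd_anthro", "sbp", 0.25)
  set_r("sd_anthro", "dbp", 0.30); set_r("sd_anthro", "insulin", 0.40)
  set_r("tg", "hdl", -0.35); set_r("tg", "glucose", 0.20)
  set_r("tg", "sbp", 0.15); set_r("tg", "dbp", 0.15)
  set_r("tg", "insulin", 0.30)
  set_r("hdl", "glucose", -0.15); set_r("hdl", "sbp", -0.10)
  set_r("hdl", "dbp", -0.10); set_r("hdl", "insulin", -0.25)
  set_r("glucose", "sbp", 0.15); set_r("glucose", "dbp", 0.15)
  set_r("glucose", "insulin", 0.35)
  set_r("sbp", "dbp", 0.70); set_r("sbp", "insulin", 0.20)
  set_r("dbp", "insulin", 0.20)
  R
}

#' Cohort configuration
#'
#' @param n_males,n_females Number of subjects per sex.
#' @param marginals Per-sex marginal table, see [default_marginals()].
#' @param corr Latent correlation matrix, see [default_correlation()]. Must be
#'   symmetric with unit diagonal and positive semi-definite.
#' @param vfm_noise_see Residual SD (standard error of estimate, grams) of
#'   measured VFM around the sex-specific anthropometric prediction equation;
#'   defaults male 30.1 g, female 22.3 g.
#' @param missing_sd_frac Fraction of subjects with the caliper-measured
#'   sagittal diameter missing (collection started mid-recruitment in the
#'   emulated study design).
#' @param bp_med_prob Per-sex probability of antihypertensive medication use.
#' @param sd_dxa_bias,sd_dxa_sd Mean and SD (cm) of the difference between the
#'   DXA-derived and caliper sagittal diameters.
#' @param target_cluster_prevalence Reference prevalence of the >= 2 non-waist
#'   risk-factor outcome the defaults were calibrated to (documentation only;
#'   not used by the generator).
#' @param seed Integer seed controlling all draws.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_males = 82, n_females = 86,
                          marginals = default_marginals(),
                          corr = default_correlation(),
                          vfm_noise_see = c(male = 30.1, female = 22.3),
                          missing_sd_frac = 0.30,
                          bp_med_prob = c(male = 0.024, female = 0),
                          sd_dxa_bias = -0.3, sd_dxa_sd = 2.0,
                          target_cluster_prevalence = c(male = 0.55,
                                                        female = 0.34),
                          seed = 1L) {
  if (n_males < 0 || n_females < 0) {
    stop_domain("sample sizes must be non-negative.", "vatmets_config_error")
  }
  if (!isTRUE(all.equal(corr, t(corr))) ||
      !isTRUE(all.equal(unname(diag(corr)), rep(1, ncol(corr))))) {
    stop_domain("correlation matrix must be symmetric with unit diagonal.",
                "vatmets_config_error")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_domain("correlation matrix is not positive semi-definite.",
                "vatmets_config_error")
  }
  for (sx in c("male", "female")) {
    m <- marginals[[sx]]
    if (!identical(m$var, cohort_vars)) {
      stop_domain("marginals must cover the standard variables in order.",
                  "vatmets_config_error")
    }
    check_positive(m$sd, "marginal sd")
  }
  structure(
    list(n_males = as.integer(n_males), n_females = as.integer(n_females),
         marginals = marginals, corr = corr, vfm_noise_see = vfm_noise_see,
         missing_sd_frac = missing_sd_frac, bp_med_prob = bp_med_prob,
         sd_dxa_bias = sd_dxa_bias, sd_dxa_sd = sd_dxa_sd,
         target_cluster_prevalence = target_cluster_prevalence,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

cohort_schema <- function() {
  tibble(
    id = integer(), sex = character(), age = numeric(), height = numeric(),
    weight = numeric(), wc = numeric(), hip = numeric(),
    suprailiac_sft = numeric(), sagittal_anthro = numeric(),
    sd_dxa = numeric(), tg = numeric(), hdl = numeric(), glucose = numeric(),
    sbp = numeric(), dbp = numeric(), on_bp_medication = logical(),
    insulin = numeric(), vfm_measured = numeric()
  )
}

generate_one_sex <- function(n, sex, config) {
  if (n == 0) {
    return(list(data = cohort_schema(), latent = matrix(0, 0, length(cohort_vars))))
  }
  marg <- config$marginals[[sex]]
  k <- length(cohort_vars)
  z <- matrix(rnorm(n * k), n, k) %*% chol(config$corr)
  colnames(z) <- cohort_vars
  obs <- z
  for (i in seq_len(k)) {
    if (marg$dist[[i]] == "lognormal") {
      obs[, i] <- exp(marg$mean[[i]] + marg$sd[[i]] * z[, i])
    } else {
      obs[, i] <- marg$mean[[i]] + marg$sd[[i]] * z[, i]
    }
  }
  obs <- pmax(obs, 0.01) # physical quantities stay positive
  age <- round_half_away(obs[, "age"])
  height <- round_half_away(obs[, "height"], 3)
  wc <- round_half_away(obs[, "wc"], 1)
  bmi <- obs[, "bmi"]
  weight <- round_half_away(bmi * height^2, 1)
  hip <- round_half_away(wc / obs[, "whr"], 1)
  sft <- round_half_away(obs[, "sft"], 1)
  sd_anthro <- round_half_away(obs[, "sd_anthro"], 1)
  sd_dxa <- round_half_away(
    sd_anthro + config$sd_dxa_bias + rnorm(n, 0, config$sd_dxa_sd), 1
  )
  miss <- runif(n) < config$missing_sd_frac
  sd_anthro[miss] <- NA_real_
  bmi_obs <- weight / height^2
  vfm <- predict_vfm(rep(sex, n), wc, bmi_obs, age) +
    rnorm(n, 0, config$vfm_noise_see[[sex]])
  bp_med <- runif(n) < config$bp_med_prob[[sex]]
  data <- tibble(
    id = seq_len(n),
    sex = sex,
    age = age,
    height = height,
    weight = weight,
    wc = wc,
    hip = hip,
    suprailiac_sft = sft,
    sagittal_anthro = sd_anthro,
    sd_dxa = sd_dxa,
    tg = round_half_away(obs[, "tg"], 2),
    hdl = round_half_away(obs[, "hdl"], 2),
    glucose = round_half_away(obs[, "glucose"], 2),
    sbp = round_half_away(obs[, "sbp"]),
    dbp = round_half_away(obs[, "dbp"]),
    on_bp_medication = bp_med,
    insulin = round_half_away(obs[, "insulin"], 1),
    vfm_measured = round_half_away(as.numeric(vfm), 1)
  )
  list(data = data, latent = z)
}

#' Generate a correlated synthetic cohort
#'
#' Draws latent multivariate-normal scores with the configured correlation,
#' maps each to its marginal (Gaussian, or log-normal for triglycerides and
#' insulin), rounds to realistic measurement precision, and derives weight
#' from BMI and height and hip circumference from the waist:hip ratio so the
#' table is internally consistent. Measured visceral fat mass is the
#' sex-specific anthropometric prediction plus Gaussian noise with the
#' configured standard error of estimate. Deterministic given the seed.
#'
#' @param config A [cohort_config()].
#' @param keep_latent Attach the latent score matrix as attribute `"latent"`
#'   (used to verify the correlation structure).
#' @return Tibble with one row per subject; columns `id`, `sex`, `age`,
#'   `height` (m), `weight` (kg), `wc`, `hip` (cm), `suprailiac_sft` (mm),
#'   `sagittal_anthro`, `sd_dxa` (cm), `tg`, `hdl`, `glucose` (mmol/L),
#'   `sbp`, `dbp` (mmHg), `on_bp_medication`, `insulin` (pmol/L),
#'   `vfm_measured` (g).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_males = 5, n_females = 5))
#' @export
generate_cohort <- function(config = cohort_config(), keep_latent = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  m <- generate_one_sex(config$n_males, "male", config)
  f <- generate_one_sex(config$n_females, "female", config)
  out <- dplyr::bind_rows(m$data, f$data)
  out$id <- seq_len(nrow(out))
  if (keep_latent) {
    attr(out, "latent") <- rbind(m$latent, f$latent)
  }
  out
}

#' Write / read a cohort CSV
#'
#' One row per subject; sex coded `"M"`/`"F"`; missing caliper sagittal
#' diameter written as an empty field.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   tibble in the internal schema.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$sex <- ifelse(out$sex == "male", "M", "F")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  out$sex <- check_sex(out$sex)
  as_tibble(out)
}
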