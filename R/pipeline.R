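# End-to-end study orchestration: simulate, derive, flag, evaluate, report.

marker_columns <- c(
  wc = "wc", whtr = "whtr", whr = "whr", conicity = "conicity",
  sd_dxa = "sd_dxa", sd_anthro = "sagittal_anthro",
  suprailiac_sft = "suprailiac_sft", bmi = "bmi", bai = "bai",
  vfm_dxa = "vfm_measured", vfm_predicted = "vfm_predicted"
)

# grid resolution at or below each measure's recording precision
default_grid_steps <- c(
  wc = 0.5, whtr = 0.005, whr = 0.005, conicity = 0.01, sd_dxa = 0.5,
  sd_anthro = 0.5, suprailiac_sft = 1, bmi = 0.25, bai = 0.5,
  vfm_dxa = 1, vfm_predicted = 1
)

#' Study configuration
#'
#' @param cohort A [cohort_config()] describing the simulated population.
#' @param markers Markers to evaluate; any of
#'   `r paste(names(marker_columns), collapse = ", ")`.
#' @param reference_marker Marker against which AUCs are compared (paired
#'   DeLong test); must be in `markers`.
#' @param outcome_threshold Number of non-waist IDF risk factors defining the
#'   positive outcome (default 2, i.e. ">= 2 non-WC factors").
#' @param grid_pairs List of 2-vectors of marker names for the joint
#'   two-threshold searches (first marker of each pair is typically `wc`).
#' @param grid_steps Named threshold resolutions for the grid searches.
#' @param out_dir Optional directory; when set, [run_study()] writes the
#'   report files there.
#' @param seed Integer seed for the whole run (overrides the cohort seed).
#' @return A `study_config` list.
#' @export
study_config <- function(cohort = cohort_config(),
                         markers = names(marker_columns),
                         reference_marker = "wc",
                         outcome_threshold = 2,
                         grid_pairs = list(c("wc", "sd_dxa"),
                                           c("wc", "suprailiac_sft"),
                                           c("wc", "bmi"),
                                           c("wc", "vfm_dxa")),
                         grid_steps = default_grid_steps,
                         out_dir = NULL, seed = 1L) {
  bad <- setdiff(markers, names(marker_columns))
  if (length(bad)) {
    stop_domain(paste0("unknown markers: ", paste(bad, collapse = ", ")),
                "vatmets_config_error")
  }
  if (!reference_marker %in% markers) {
    stop_domain("`reference_marker` must be one of `markers`.",
                "vatmets_config_error")
  }
  if (!outcome_threshold %in% 1:4) {
    stop_domain("`outcome_threshold` must be 1, 2, 3 or 4.",
                "vatmets_config_error")
  }
  for (pair in grid_pairs) {
    if (length(pair) != 2 || !all(pair %in% markers)) {
      stop_domain("each grid pair must name two configured markers.",
                  "vatmets_config_error")
    }
  }
  structure(
    list(cohort = cohort, markers = markers,
         reference_marker = reference_marker,
         outcome_threshold = as.integer(outcome_threshold),
         grid_pairs = grid_pairs, grid_steps = grid_steps,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "study_config"
  )
}

log_stage <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full study pipeline
#'
#' Simulates the cohort, derives anthropometric indices and predicted VFM,
#' flags IDF risk factors, evaluates every configured marker per sex (ROC
#' with AUC confidence interval and paired comparison against the reference
#' marker, Youden and product cut-points with threshold metrics,
#' precision-recall curves) and runs the configured joint two-threshold
#' accuracy searches. Complete-case handling is per marker, so markers with
#' missing values (e.g. the caliper sagittal diameter) are evaluated on their
#' measured subset. Idempotent for a fixed seed. Progress is logged to
#' standard error; results never are.
#'
#' @param config A [study_config()].
#' @param quiet Suppress progress messages.
#' @return Object of class `report_bundle`: list with `cohort` (the derived
#'   subject table), `marker_table` (one row per sex and marker: `n`, `auc`,
#'   `ci_low`, `ci_high`, `p_vs_reference`, `cutpoint` and integer-percent
#'   threshold metrics), `combined_rules` (one row per sex and grid pair with
#'   both cut-points and metrics including F1), `roc_points`, `pr_points`,
#'   `grid_accuracy` (long format for contours) and `manifest`.
#' @export
run_study <- function(config = study_config(), quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- config$seed
  log_stage(quiet, "simulate", "generating cohort (%d male, %d female), seed %d",
            cohort_cfg$n_males, cohort_cfg$n_females, config$seed)
  cohort <- generate_cohort(cohort_cfg)
  cohort <- anthro_indices(cohort)
  cohort$vfm_predicted <- as.numeric(
    predict_vfm(cohort$sex, cohort$wc, cohort$bmi, cohort$age)
  )
  cohort <- flag_risk_factors(cohort)
  cohort$outcome <- cohort$non_wc_count >= config$outcome_threshold

  marker_rows <- list()
  roc_points <- list()
  pr_points <- list()
  for (sx in c("male", "female")) {
    d <- cohort[cohort$sex == sx, ]
    ref_col <- marker_columns[[config$reference_marker]]
    for (mk in config$markers) {
      col <- marker_columns[[mk]]
      dm <- d[!is.na(d[[col]]), ]
      log_stage(quiet, "evaluate", "%s %s: n = %d complete cases",
                sx, mk, nrow(dm))
      roc <- roc_curve(dm, !!rlang::sym("outcome"), !!rlang::sym(col))
      pr <- pr_curve(dm, !!rlang::sym("outcome"), !!rlang::sym(col))
      p_ref <- NA_real_
      if (mk != config$reference_marker) {
        both <- d[!is.na(d[[col]]) & !is.na(d[[ref_col]]), ]
        p_ref <- compare_auc_paired(both[[col]], both[[ref_col]],
                                    both$outcome)$p_value
      }
      y <- roc$youden
      marker_rows[[length(marker_rows) + 1]] <- tibble(
        sex = sx, marker = mk, n = nrow(dm),
        auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
        p_vs_reference = p_ref,
        cutpoint = y$cutpoint,
        sensitivity = y$sensitivity_pct, specificity = y$specificity_pct,
        ppv = y$ppv_pct, npv = y$npv_pct, accuracy = y$accuracy_pct
      )
      roc_points[[length(roc_points) + 1]] <-
        dplyr::mutate(roc$points, sex = sx, marker = mk, .before = 1)
      pr_points[[length(pr_points) + 1]] <-
        dplyr::mutate(pr$points, sex = sx, marker = mk, .before = 1)
    }
  }

  combined_rows <- list()
  grid_long <- list()
  for (sx in c("male", "female")) {
    d <- cohort[cohort$sex == sx, ]
    for (pair in config$grid_pairs) {
      c1 <- marker_columns[[pair[[1]]]]
      c2 <- marker_columns[[pair[[2]]]]
      log_stage(quiet, "grid-search", "%s: %s x %s", sx, pair[[1]], pair[[2]])
      gs <- joint_threshold_grid(
        d, !!rlang::sym("outcome"), !!rlang::sym(c1), !!rlang::sym(c2),
        step1 = config$grid_steps[[pair[[1]]]],
        step2 = config$grid_steps[[pair[[2]]]]
      )
      b <- gs$best
      combined_rows[[length(combined_rows) + 1]] <- tibble(
        sex = sx, marker1 = pair[[1]], marker2 = pair[[2]],
        cutpoint1 = b$threshold1, cutpoint2 = b$threshold2,
        sensitivity = b$sensitivity_pct, specificity = b$specificity_pct,
        ppv = b$ppv_pct, npv = b$npv_pct, accuracy = b$accuracy_pct,
        f1 = b$f1_pct
      )
      lg <- tidy(gs)
      names(lg)[1:2] <- c("threshold1", "threshold2")
      grid_long[[length(grid_long) + 1]] <- dplyr::mutate(
        lg, sex = sx, marker1 = pair[[1]], marker2 = pair[[2]], .before = 1
      )
    }
  }

  manifest <- list(
    package = "vatmets",
    version = as.character(utils::packageVersion("vatmets")),
    seed = config$seed,
    n_males = cohort_cfg$n_males, n_females = cohort_cfg$n_females,
    markers = config$markers,
    reference_marker = config$reference_marker,
    outcome_threshold = config$outcome_threshold,
    grid_pairs = lapply(config$grid_pairs, paste, collapse = " x ")
  )
  bundle <- structure(
    list(
      cohort = cohort,
      marker_table = dplyr::bind_rows(marker_rows),
      combined_rules = dplyr::bind_rows(combined_rows),
      roc_points = dplyr::bind_rows(roc_points),
      pr_points = dplyr::bind_rows(pr_points),
      grid_accuracy = dplyr::bind_rows(grid_long),
      manifest = manifest
    ),
    class = "report_bundle"
  )
  if (!is.null(config$out_dir)) {
    write_report_bundle(bundle, config$out_dir, quiet = quiet)
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d subjects, %d marker rows, %d combined rules\n",
              nrow(x$cohort), nrow(x$marker_table), nrow(x$combined_rules)))
  print(x$marker_table)
  invisible(x)
}

#' Write a report bundle to plain-text files
#'
#' @param bundle A `report_bundle` from [run_study()].
#' @param dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(bundle, dir, quiet = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  log_stage(quiet, "report", "writing bundle to %s", dir)
  write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  readr::write_csv(bundle$marker_table, file.path(dir, "marker_table.csv"), na = "")
  readr::write_csv(bundle$combined_rules, file.path(dir, "combined_rules.csv"))
  readr::write_csv(bundle$roc_points, file.path(dir, "roc_points.csv"))
  readr::write_csv(bundle$pr_points, file.path(dir, "pr_points.csv"))
  readr::write_csv(bundle$grid_accuracy, file.path(dir, "grid_accuracy.csv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write the packaged test fixtures
#'
#' Generates the small reference data set used by the test suite: a cohort of
#' 168 subjects (82 male, 86 female) and three abdominal phantoms spanning
#' lean, average and obese geometry, each with its analytic truth sidecar.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- generate_cohort(cohort_config(seed = seed))
  paths <- character()
  p <- file.path(dir, "cohort.csv")
  write_cohort(cohort, p)
  paths <- c(paths, p)
  geoms <- list(
    lean = phantom_config(width = 24, sagittal = 18, sfl_thickness = 1.2,
                          sfl_fat_fraction = 0.75, visceral_fat_fraction = 0.25,
                          seed = seed),
    average = phantom_config(width = 30, sagittal = 22, sfl_thickness = 2.0,
                             sfl_fat_fraction = 0.80, visceral_fat_fraction = 0.30,
                             seed = seed),
    obese = phantom_config(width = 36, sagittal = 26, sfl_thickness = 3.0,
                           sfl_fat_fraction = 0.85, visceral_fat_fraction = 0.40,
                           seed = seed)
  )
  for (nm in names(geoms)) {
    ph <- generate_phantom(geoms[[nm]])
    paths <- c(paths, write_phantom(ph, dir, paste0("phantom_", nm)))
  }
  invisible(paths)
}
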