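# Anthropometric indices, prediction equations, IDF flagging.

test_that("indices evaluate their defining formulas", {
  d <- anthro_indices(tibble::tibble(height = 1.70, weight = 70,
                                     wc = 90, hip = 100))
  expect_equal(d$bmi, 70 / 1.70^2)
  expect_equal(d$whtr, 90 / 170)
  expect_equal(d$whr, 0.90)
  expect_equal(d$conicity, 0.90 / (0.109 * sqrt(70 / 1.70)), tolerance = 1e-10)
  expect_equal(round(d$conicity, 3), 1.287)
  # body adiposity index with sqrt(1.69) = 1.3 exactly
  d2 <- anthro_indices(tibble::tibble(height = 1.69, weight = 70,
                                      wc = 90, hip = 100))
  expect_equal(d2$bai, 100 / 1.69^1.5 - 18, tolerance = 1e-10)
  expect_equal(round(d2$bai, 2), 27.52)
  # unit height: bai degenerates to hip - 18
  d3 <- anthro_indices(tibble::tibble(height = 1, weight = 60,
                                      wc = 80, hip = 95))
  expect_equal(d3$bai, 95 - 18)
  expect_error(
    anthro_indices(tibble::tibble(height = 0, weight = 70, wc = 90, hip = 100)),
    class = "vatmets_domain_error"
  )
})

test_that("the printed prediction equations are reproduced", {
  expect_equal(unclass(vfm_equation("male")),
               c(wc = 2.248, bmi = 4.441, age = 1.013, intercept = -227.773),
               ignore_attr = TRUE)
  expect_equal(unclass(vfm_equation("female")),
               c(wc = 1.415, bmi = 3.381, age = 0.599, intercept = -129.803),
               ignore_attr = TRUE)
  expect_equal(attr(vfm_equation("male"), "see"), 30.1)
  expect_equal(attr(vfm_equation("female"), "see"), 22.3)
  v <- predict_vfm("male", wc = 92, bmi = 25, age = 45)
  expect_equal(as.numeric(v), 2.248 * 92 + 4.441 * 25 + 1.013 * 45 - 227.773)
  expect_equal(round(as.numeric(v), 2), 135.65)
  expect_false(attr(v, "out_of_range"))
  # intercept probe: all predictors zero, negative and flagged
  probe <- predict_vfm("female", 0, 0, 0)
  expect_equal(as.numeric(probe), -129.803)
  expect_true(attr(probe, "out_of_range"))
  expect_error(predict_vfm("other", 90, 25, 40), class = "vatmets_domain_error")
})

test_that("predict_vfm is affine in its inputs", {
  set.seed(3)
  for (i in 1:20) {
    x <- c(runif(1, 70, 110), runif(1, 18, 35), runif(1, 20, 70))
    y <- c(runif(1, 70, 110), runif(1, 18, 35), runif(1, 20, 70))
    a <- runif(1)
    mix <- a * x + (1 - a) * y
    lhs <- predict_vfm("male", mix[1], mix[2], mix[3])
    rhs <- a * predict_vfm("male", x[1], x[2], x[3]) +
      (1 - a) * predict_vfm("male", y[1], y[2], y[3])
    expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-10)
  }
})

test_that("IDF thresholds have exact boundary semantics", {
  base <- tibble::tibble(
    sex = "male", wc = 85, tg = 1.0, hdl = 1.5, glucose = 5.0,
    sbp = 120, dbp = 70, on_bp_medication = FALSE
  )
  flag_of <- function(row, flag) flag_risk_factors(row)[[flag]]
  probe <- function(col, cut, flag, sex = "male", geq = TRUE) {
    eps <- 1e-6
    at <- base
    at$sex <- sex
    at[[col]] <- cut
    below <- at
    below[[col]] <- cut - eps
    above <- at
    above[[col]] <- cut + eps
    if (geq) { # criterion is >=: true at and above the cut
      expect_true(flag_of(at, flag))
      expect_false(flag_of(below, flag))
      expect_true(flag_of(above, flag))
    } else { # criterion is strict <: false at the cut
      expect_false(flag_of(at, flag))
      expect_true(flag_of(below, flag))
      expect_false(flag_of(above, flag))
    }
  }
  probe("tg", 1.69, "high_tg")
  probe("hdl", 1.04, "low_hdl", sex = "male", geq = FALSE)
  probe("hdl", 1.29, "low_hdl", sex = "female", geq = FALSE)
  probe("glucose", 5.6, "high_glucose")
  probe("sbp", 130, "high_bp")
  probe("dbp", 85, "high_bp")
  probe("wc", 90, "large_wc", sex = "male")
  probe("wc", 80, "large_wc", sex = "female")
  # medication alone raises the blood-pressure flag
  med <- base
  med$on_bp_medication <- TRUE
  expect_true(flag_of(med, "high_bp"))
})

test_that("risk factor profiles count non-waist factors and define MetS", {
  subj <- tibble::tibble(
    sex = "male", wc = 95.6, tg = 2.4, hdl = 1.0, glucose = 5.4,
    sbp = 124, dbp = 77, on_bp_medication = FALSE
  )
  f <- flag_risk_factors(subj)
  expect_true(f$high_tg)
  expect_true(f$low_hdl)
  expect_false(f$high_bp)
  expect_false(f$high_glucose)
  expect_identical(f$non_wc_count, 2L)
  expect_true(f$large_wc)
  expect_true(f$mets)
  expect_true(f$cluster_outcome)
  healthy <- tibble::tibble(
    sex = "female", wc = 75, tg = 1.0, hdl = 1.6, glucose = 4.8,
    sbp = 110, dbp = 70, on_bp_medication = FALSE
  )
  h <- flag_risk_factors(healthy)
  expect_identical(h$non_wc_count, 0L)
  expect_false(h$mets)
  # missing columns are named in the error
  expect_error(flag_risk_factors(subj[, setdiff(names(subj), "hdl")]),
               "hdl", class = "vatmets_missing_error")
  # absent medication column defaults to FALSE with a message
  expect_message(
    nf <- flag_risk_factors(subj[, setdiff(names(subj), "on_bp_medication")]),
    "medication"
  )
  expect_identical(nf$non_wc_count, 2L)
})

test_that("flagging is deterministic and order-independent", {
  set.seed(9)
  co <- suppressMessages(generate_cohort(cohort_config(n_males = 40,
                                                       n_females = 40,
                                                       seed = 5)))
  f1 <- flag_risk_factors(co)
  perm <- sample(nrow(co))
  f2 <- flag_risk_factors(co[perm, ])
  expect_identical(f2$non_wc_count, f1$non_wc_count[perm])
  expect_identical(f2$mets, f1$mets[perm])
})
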