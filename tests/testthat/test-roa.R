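test_that("trial filtering keeps the requested frequency and signs motion by direction", {
  tr <- data.frame(
    trial_id = 1:6, session_id = 1,
    nerve = "fn", direction = c("cw", "cw", "cw", "ccw", "ccw", "cw"),
    hip_shift_cm = 0, start_angle_deg = c(0, 15, 30, 45, 60, 75),
    freq_hz = c(100, 40, 100, 100, 100, 100),
    pulse_width_us = 125, amplitude_ma = 4,
    deviation_deg = c(25, 90, 9.9, -12, 12, -40)
  )
  out <- filter_trials(tr, freq_hz = 100)
  expect_equal(out$trial_id, c(1L, 3L, 4L, 5L, 6L))
  # 9.9 degrees is below the strict 10 degree motion rule
  expect_identical(out$motion_observed, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(filter_trials(tr, freq_hz = 100, direction = "ccw")$trial_id,
               4:5)
  expect_warning(filter_trials(tr, freq_hz = 60), "no trials match")
  expect_error(filter_trials(tr[, -4]), class = "fescycle_bad_trials")
})

test_that("degenerate and outlier cases of the RoA estimator", {
  est <- estimate_roa(rep(30, 5))
  expect_equal(unclass(est$region), unclass(region_set(c(22.5, 37.5))))
  expect_equal(est$coverage_achieved, 1)
  expect_equal(est$n_trials_used, 5L)

  # 19 observations clustered in [90, 180] plus a single outlier at 300:
  # the 95 percent arc keeps the cluster and drops the outlier
  withr::with_seed(5, ang <- c(stats::runif(19, 90, 180), 300))
  est <- estimate_roa(ang, coverage = 0.95, pad_deg = 0)
  expect_false(region_contains(est$region, 300))
  expect_true(all(region_contains(est$region, ang[ang <= 180][-which.max(ang[ang <= 180])])))
  expect_gte(est$coverage_achieved, 0.95)

  expect_error(estimate_roa(numeric(0)), class = "fescycle_no_motion_trials")
})

test_that("the estimator equals exhaustive observation-anchored search", {
  withr::with_seed(99, {
    for (i in 1:20) {
      n <- sample(3:50, 1)
      # mix of clustered and uniform angles, with duplicates
      ang <- c(stats::rnorm(n %/% 2, mean = stats::runif(1, 0, 360), sd = 25),
               stats::runif(n - n %/% 2, 0, 360)) %% 360
      if (i %% 3 == 0) ang <- round(ang / 15) * 15 %% 360
      cov <- sample(c(0.8, 0.9, 0.95, 1), 1)
      est <- estimate_roa(ang, coverage = cov, pad_deg = 0)
      oracle <- brute_roa(ang, coverage = cov)
      expect_equal(est$arc_start, unname(oracle["start"]) %% 360,
                   tolerance = 1e-9)
      expect_equal(region_measure(est$region), unname(oracle["width"]),
                   tolerance = 1e-9)
    }
  })
})

test_that("confusion measures partition the circle and match worked examples", {
  m <- roa_confusion(region_set(c(0, 90)), region_set(c(0, 90)))
  expect_equal(unlist(m[c("tp_deg", "tn_deg", "fp_deg", "fn_deg")]),
               c(tp_deg = 90, tn_deg = 270, fp_deg = 0, fn_deg = 0))
  r <- agreement_ratios(m)
  expect_equal(c(r$sensitivity, r$specificity, r$ppv, r$npv), rep(1, 4))

  m2 <- agreement_ratios(roa_confusion(region_set(c(0, 100)),
                                       region_set(c(50, 150))))
  expect_equal(m2$tp_deg, 50)
  expect_equal(m2$fp_deg, 50)
  expect_equal(m2$fn_deg, 50)
  expect_equal(m2$tn_deg, 210)
  expect_equal(m2$sensitivity, 0.5)
  expect_equal(m2$specificity, 210 / 260)
  expect_equal(m2$ppv, 0.5)
  expect_equal(m2$npv, 210 / 260)

  m3 <- roa_confusion(region_set(c(0, 50)), region_set(c(100, 150)))
  expect_equal(m3$tp_deg, 0)
})

test_that("an empty model region yields undefined PPV, zero sensitivity", {
  r <- agreement_ratios(roa_confusion(empty_region(), region_set(c(0, 90))))
  expect_true(is.na(r$ppv))
  expect_equal(r$sensitivity, 0)
  expect_equal(r$specificity, 1)
})

test_that("confusion is symmetric under swapping model and experiment", {
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- region_set(rand_arcs(3))
      b <- region_set(rand_arcs(3))
      ab <- agreement_ratios(roa_confusion(a, b))
      ba <- agreement_ratios(roa_confusion(b, a))
      expect_equal(ab$fp_deg, ba$fn_deg)
      expect_equal(ab$fn_deg, ba$fp_deg)
      expect_equal(ab$sensitivity, ba$ppv)
      expect_equal(ab$specificity, ba$npv)
      expect_equal(ab$tp_deg + ab$tn_deg + ab$fp_deg + ab$fn_deg, 360,
                   tolerance = 1e-9)
    }
  })
})

test_that("aggregation uses the sample SD and flags undefined entries", {
  rows <- data.frame(sensitivity = c(0, 1), specificity = c(0.5, 0.5),
                     ppv = c(NA, 0.8), npv = c(0.9, 0.7))
  expect_message(agg <- aggregate_metrics(rows), "1 undefined ppv")
  s <- agg$summary
  expect_equal(s$mean[s$metric == "sensitivity"], 0.5)
  expect_equal(s$sd[s$metric == "sensitivity"], sqrt(0.5), tolerance = 1e-12)
  expect_equal(s$sd[s$metric == "specificity"], 0)
  expect_equal(s$n_used[s$metric == "ppv"], 1L)
  expect_equal(s$n_missing[s$metric == "ppv"], 1L)
  expect_true(is.na(s$sd[s$metric == "ppv"]))
  expect_error(aggregate_metrics(rows[1, ]), class = "fescycle_bad_metrics")
})

test_that("trial CSVs round-trip and schema violations name the rows", {
  tr <- generate_trials(default_study_design(seed = 3))$trials
  f <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, f)
  back <- read_trials(f)
  expect_equal(back$deviation_deg, tr$deviation_deg)
  expect_equal(back$start_angle_deg, tr$start_angle_deg)

  bad <- tr
  bad$nerve[3] <- "xx"
  expect_error(write_trials(bad, f), "row\\(s\\) 3")
  bad <- tr
  bad$start_angle_deg[5] <- 400
  expect_error(write_trials(bad, f), class = "fescycle_bad_trials")
})
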