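truth_demo <- function() {
  list(fn_cw = region_set(c(30, 140)), sn_cw = region_set(c(160, 280)))
}

test_that("generator configuration enforces its invariants", {
  expect_error(trial_generator_config(truth_demo()),
               class = "fescycle_bad_config")
  expect_error(trial_generator_config(list(bad = region_set(c(0, 10))), seed = 1),
               class = "fescycle_bad_config")
  expect_error(trial_generator_config(truth_demo(), seed = 1, grid_step_deg = 14),
               class = "fescycle_bad_config")
  expect_error(trial_generator_config(truth_demo(), seed = 1,
                                      inside_motion_prob = 1.2),
               class = "fescycle_bad_config")
  expect_error(trial_generator_config(list(fn_cw = empty_region()), seed = 1),
               class = "fescycle_bad_config")
  expect_s3_class(trial_generator_config(truth_demo(), seed = 1),
                  "trial_generator_config")
})

test_that("the same seed reproduces the trial table; different seeds differ", {
  cfg1 <- trial_generator_config(truth_demo(), seed = 7)
  a <- generate_trials(cfg1)
  b <- generate_trials(cfg1)
  expect_identical(a$trials, b$trials)
  cfg2 <- trial_generator_config(truth_demo(), seed = 8)
  c <- generate_trials(cfg2)
  expect_false(identical(a$trials$start_angle_deg, c$trials$start_angle_deg))
})

test_that("a noise-free generator puts motion only inside the truth region", {
  cfg <- trial_generator_config(truth_demo(), seed = 5,
                                outside_motion_prob = 0, noise_sd_deg = 0)
  sim <- generate_trials(cfg)
  tr <- filter_trials(sim$trials, freq_hz = NULL)
  moved <- tr[tr$motion_observed, ]
  expect_gt(nrow(moved), 0)
  for (nerve in c("fn", "sn")) {
    inside <- region_contains(truth_demo()[[paste0(nerve, "_cw")]],
                              moved$start_angle_deg[moved$nerve == nerve])
    expect_true(all(inside))
  }
})

test_that("inside-region motion frequency matches the configured probability", {
  cfg <- trial_generator_config(truth_demo(), seed = 11, reps_per_angle = 12,
                                hip_shifts_cm = 0)
  sim <- generate_trials(cfg)
  tr <- filter_trials(sim$trials, freq_hz = 100, nerve = "fn")
  inside <- region_contains(truth_demo()$fn_cw, tr$start_angle_deg)
  n <- sum(inside)
  phat <- mean(tr$motion_observed[inside])
  ci <- 1.96 * sqrt(0.95 * 0.05 / n)
  expect_lt(abs(phat - 0.95), ci + 0.02)
  # off the primary frequency the motion rate is attenuated
  tr40 <- filter_trials(sim$trials, freq_hz = 40, nerve = "fn")
  expect_lt(mean(tr40$motion_observed[region_contains(truth_demo()$fn_cw,
                                                      tr40$start_angle_deg)]),
            phat)
})

test_that("the default study design echoes the campaign's size and shape", {
  des <- default_study_design(seed = 2)
  expect_s3_class(des, "trial_generator_config")
  n <- expected_trial_count(des)
  expect_gte(n, 669)
  expect_lte(n, 817)
  sim <- generate_trials(des)
  expect_equal(nrow(sim$trials), n)
  # centred trials dominate, matching the emulated protocol
  expect_gt(mean(sim$trials$hip_shift_cm == 0), 0.7)
  # manifest bookkeeping matches the emitted table
  counts <- sim$manifest$condition_counts
  for (i in seq_len(nrow(counts))) {
    got <- sum(sim$trials$nerve == counts$nerve[i] &
                 sim$trials$direction == counts$direction[i] &
                 sim$trials$hip_shift_cm == counts$hip_shift_cm[i])
    expect_equal(got, counts$Freq[i])
  }
})

test_that("expected counts grow monotonically with repetitions", {
  ns <- vapply(1:4, function(r) {
    expected_trial_count(trial_generator_config(truth_demo(), seed = 1,
                                                reps_per_angle = r))
  }, integer(1))
  expect_true(all(diff(ns) > 0))
})

test_that("low-noise trials recover the truth regions", {
  truth <- truth_demo()
  cfg <- trial_generator_config(truth, seed = 31, reps_per_angle = 5,
                                noise_sd_deg = 2, outside_motion_prob = 0.002,
                                hip_shifts_cm = 0)
  sim <- generate_trials(cfg)
  for (nerve in c("fn", "sn")) {
    tr <- filter_trials(sim$trials, freq_hz = 100, nerve = nerve,
                        direction = "cw")
    est <- estimate_roa(tr$start_angle_deg[tr$motion_observed])
    tt <- truth[[paste0(nerve, "_cw")]]
    jacc <- region_measure(region_intersect(est$region, tt)) /
      region_measure(region_union(est$region, tt))
    expect_gte(jacc, 0.9)
  }
})

test_that("more outside-region motion degrades recovered specificity", {
  spec_at <- function(p_out) {
    vals <- vapply(1:4, function(s) {
      cfg <- trial_generator_config(truth_demo()["fn_cw"], seed = 100 + s,
                                    reps_per_angle = 4,
                                    outside_motion_prob = p_out,
                                    hip_shifts_cm = 0)
      sim <- generate_trials(cfg)
      tr <- filter_trials(sim$trials, freq_hz = 100)
      est <- estimate_roa(tr$start_angle_deg[tr$motion_observed])
      agreement_ratios(roa_confusion(est$region, truth_demo()$fn_cw))$specificity
    }, numeric(1))
    mean(vals)
  }
  s <- vapply(c(0, 0.15, 0.4), spec_at, numeric(1))
  expect_gt(s[1], s[2] - 0.01)
  expect_gt(s[2], s[3] - 0.01)
  expect_gt(s[1], s[3])
})
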