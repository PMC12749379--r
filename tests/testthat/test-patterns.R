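# dense-grid thresholding oracle: arcs where the signal exceeds eps,
# reconstructed by run-length encoding on a 0.01-degree grid
grid_threshold_region <- function(signal, eps, step = 0.01) {
  q <- seq(0, 360 - step, by = step)
  on <- signal(q) > eps
  if (!any(on)) return(empty_region())
  if (all(on)) return(full_circle())
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  region_set(cbind(q[starts[r$values]], q[ends[r$values]] + step))
}

sym_diff_measure <- function(a, b) {
  region_measure(region_union(region_diff(a, b), region_diff(b, a)))
}

test_that("pattern configuration validates its inputs", {
  expect_error(pattern_config(epsilon = c(XX = 1)), class = "fescycle_bad_config")
  expect_error(pattern_config(epsilon = c(fn = -1)), class = "fescycle_bad_config")
  expect_error(pattern_config(epsilon_frac = 0), class = "fescycle_bad_config")
  expect_error(pattern_config(crank_weights = c(1, 1)), class = "fescycle_bad_config")
  expect_error(pattern_config(crank_weights = c(1, 0, 1)), class = "fescycle_bad_config")
  expect_error(pattern_config(overlap_policy = "nope"))
})

test_that("an over-large threshold is rejected as infeasible", {
  g <- test_geom()
  tt <- torque_transfer(seq(0, 359.9, by = 0.1), g)
  eps_bad <- 1.01 * max(abs(tt$T_hip))
  cfg <- pattern_config(epsilon = c(GM = eps_bad))
  expect_error(muscle_regions(g, cfg, "cw"),
               class = "fescycle_epsilon_infeasible")
})

test_that("muscle regions match dense-grid thresholding of the ratios", {
  g <- test_geom()
  cfg <- pattern_config()
  for (dirn in c("cw", "ccw")) {
    pat <- muscle_regions(g, cfg, dirn)
    for (tg in c("GM", "QM", "HM", "PFM")) {
      sig <- fescycle:::target_signal(tg, g, dirn, cfg$crank_weights)
      oracle <- grid_threshold_region(sig, pat$epsilon[[tg]])
      expect_lt(sym_diff_measure(pat$regions[[tg]], oracle), 0.1)
    }
  }
})

test_that("a vanishing QM threshold recovers the negative-knee-ratio set", {
  g <- test_geom()
  cfg <- pattern_config(epsilon = c(QM = 1e-9, GM = 1e-9, HM = 1e-9,
                                    PFM = 1e-9))
  pat <- muscle_regions(g, cfg, "cw")
  sig <- function(q) -torque_transfer(q, g)$T_knee
  expect_lt(sym_diff_measure(pat$regions$QM, grid_threshold_region(sig, 0)),
            0.1)
})

test_that("with equal weights and tiny threshold the sciatic region is where S_h + S_a > 0", {
  g <- test_geom()
  cfg <- pattern_config(epsilon = c(sn = 1e-9))
  pat <- nerve_regions(g, cfg, "cw")
  sig <- function(q) {
    s <- velocity_transforms(q, g)
    s$S_h + s$S_a
  }
  oracle <- grid_threshold_region(sig, 0)
  # the built sciatic region is the oracle set minus the femoral claim
  expect_lt(sym_diff_measure(pat$regions$sn,
                             region_diff(oracle, pat$regions$fn)), 0.1)
})

test_that("femoral and sciatic regions are disjoint under every overlap policy", {
  g <- test_geom()
  for (policy in c("femoral_priority", "sciatic_priority", "split_midpoint")) {
    for (dirn in c("cw", "ccw")) {
      pat <- nerve_regions(g, pattern_config(overlap_policy = policy), dirn)
      expect_equal(region_measure(region_intersect(pat$regions$fn,
                                                   pat$regions$sn)), 0,
                   tolerance = 1e-9)
      expect_gt(region_measure(pat$regions$fn), 0)
      expect_gt(region_measure(pat$regions$sn), 0)
    }
  }
})

test_that("overlap policies redistribute, never invent, stimulated angles", {
  g <- test_geom()
  pats <- lapply(c("femoral_priority", "sciatic_priority", "split_midpoint"),
                 function(p) nerve_regions(g, pattern_config(overlap_policy = p), "cw"))
  unions <- lapply(pats, function(p) region_union(p$regions$fn, p$regions$sn))
  for (i in 2:3)
    expect_lt(sym_diff_measure(unions[[1]], unions[[i]]), 1e-6)
})

test_that("nerve regions match the dense-grid oracle with overlap removal", {
  g <- test_geom()
  cfg <- pattern_config()
  pat <- nerve_regions(g, cfg, "cw")
  fn_sig <- fescycle:::target_signal("fn", g, "cw", cfg$crank_weights)
  sn_sig <- fescycle:::target_signal("sn", g, "cw", cfg$crank_weights)
  fn_o <- grid_threshold_region(fn_sig, pat$epsilon[["fn"]])
  sn_o <- region_diff(grid_threshold_region(sn_sig, pat$epsilon[["sn"]]), fn_o)
  expect_lt(sym_diff_measure(pat$regions$fn, fn_o), 0.1)
  expect_lt(sym_diff_measure(pat$regions$sn, sn_o), 0.1)
})

test_that("raising a threshold never enlarges its region", {
  g <- test_geom()
  prev <- NULL
  for (frac in c(0.05, 0.15, 0.3, 0.6)) {
    pat <- nerve_regions(g, pattern_config(epsilon_frac = frac), "cw")
    if (!is.null(prev)) {
      expect_equal(region_measure(region_diff(pat$regions$fn, prev)), 0,
                   tolerance = 1e-6)
    }
    prev <- pat$regions$fn
  }
})

test_that("clockwise and counterclockwise regions complement up to the dead bands", {
  g <- test_geom()
  cfg <- pattern_config(epsilon = c(fn = 0.05))
  cw <- nerve_regions(g, cfg, "cw")$regions$fn
  ccw <- nerve_regions(g, cfg, "ccw")$regions$fn
  expect_equal(region_measure(region_intersect(cw, ccw)), 0, tolerance = 1e-9)
  # the uncovered remainder is exactly the |signal| <= eps band
  band <- region_complement(region_union(cw, ccw))
  sig <- fescycle:::target_signal("fn", g, "cw", cfg$crank_weights)
  band_oracle <- grid_threshold_region(function(q) -abs(sig(q)), -0.05)
  expect_lt(sym_diff_measure(band, band_oracle), 0.1)
})

test_that("the left-leg pattern is the right pattern rotated half a turn", {
  g <- test_geom()
  pat <- nerve_regions(g, pattern_config(), "cw")
  left <- left_pattern_from_right(pat)
  expect_equal(left$side, "left")
  for (tg in names(pat$regions)) {
    expect_equal(unclass(left$regions[[tg]]),
                 unclass(region_rotate(pat$regions[[tg]], 180)),
                 tolerance = 1e-12)
    expect_equal(region_measure(left$regions[[tg]]),
                 region_measure(pat$regions[[tg]]), tolerance = 1e-12)
  }
  back <- left_pattern_from_right(left)
  expect_equal(back$side, "right")
  expect_equal(lapply(back$regions, unclass), lapply(pat$regions, unclass),
               tolerance = 1e-12)
})

test_that("activation queries honour the stored half-open arcs", {
  g <- test_geom()
  pat <- nerve_regions(g, pattern_config(), "cw")
  fn <- pat$regions$fn
  expect_true(is_active(pat, "fn", fn[1, "start"]))
  expect_false(is_active(pat, "fn", fn[1, "end"]))
  expect_error(is_active(pat, "GM", 10), class = "fescycle_bad_target")
  # a grid sweep of activation states reproduces the region
  qs <- seq(0, 359.9, by = 0.1)
  on <- is_active(pat, "fn", qs)
  expect_identical(on, region_contains(fn, qs))
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  swept <- region_set(cbind(qs[starts[r$values]], qs[ends[r$values]] + 0.1))
  expect_lt(sym_diff_measure(swept, fn), 0.25)
})

test_that("the gluteal/quadriceps overlap diagnostic is a plain fraction", {
  pat <- muscle_regions(test_geom(), pattern_config(), "cw")
  d <- pattern_overlap_diagnostic(pat)
  expect_true(is.finite(d) && d >= 0)
  patB <- nerve_regions(test_geom(), pattern_config(), "cw")
  expect_error(pattern_overlap_diagnostic(patB), class = "fescycle_bad_target")
})
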