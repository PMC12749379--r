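# Stimulation-pattern construction: translate torque-transfer profiles into
# crank-angle switching regions for the four-muscle model (version A) and
# the two-nerve model (version B).

#' Configuration for stimulation-pattern construction
#'
#' @param epsilon Optional named numeric vector of absolute activation
#'   thresholds per target (names among `GM`, `QM`, `HM`, `PFM`, `fn`,
#'   `sn`), each `> 0`.  Targets without an entry use
#'   `epsilon_frac * max(|relevant torque-transfer ratio|)` over the cycle.
#'   A threshold at or above the cycle maximum of its signal leaves the
#'   region empty and raises a `fescycle_epsilon_infeasible` error at
#'   pattern-build time.
#' @param epsilon_frac Fraction of the cycle-maximum ratio magnitude used as
#'   the default threshold (default 0.1, i.e. 10 percent).
#' @param crank_weights Positive weights `(a1, a2, a3)` combining the hip,
#'   knee and ankle torque-transfer ratios into the crank ratio used for the
#'   sciatic region; defaults to `c(1, 1, 1)`.
#' @param grid_step Evaluation grid step in degrees (default 0.1); region
#'   boundaries are refined by bisection to `1e-4` degrees, so results are
#'   grid independent.
#' @param overlap_policy How version B removes femoral/sciatic overlap so
#'   the two nerves are never co-stimulated: `"femoral_priority"` subtracts
#'   the overlap from the sciatic region (default), `"sciatic_priority"`
#'   from the femoral region, `"split_midpoint"` splits each overlap arc at
#'   its midpoint, each nerve keeping the half adjacent to its own
#'   exclusive territory.
#' @return An object of class `pattern_config`.
#' @export
pattern_config <- function(epsilon = NULL, epsilon_frac = 0.1,
                           crank_weights = c(1, 1, 1), grid_step = 0.1,
                           overlap_policy = c("femoral_priority",
                                              "sciatic_priority",
                                              "split_midpoint")) {
  overlap_policy <- match.arg(overlap_policy)
  targets <- c("GM", "QM", "HM", "PFM", "fn", "sn")
  if (!is.null(epsilon)) {
    if (is.null(names(epsilon)) || !all(names(epsilon) %in% targets))
      stop_fescycle("bad_config",
                    "epsilon must be a named vector with names among GM, QM, HM, PFM, fn, sn")
    if (any(!is.finite(epsilon)) || any(epsilon <= 0))
      stop_fescycle("bad_config", "epsilon thresholds must be positive and finite")
  }
  if (!is.numeric(epsilon_frac) || length(epsilon_frac) != 1L ||
      epsilon_frac <= 0 || epsilon_frac >= 1)
    stop_fescycle("bad_config", "epsilon_frac must be in (0, 1)")
  if (length(crank_weights) != 3L || any(!is.finite(crank_weights)) ||
      any(crank_weights <= 0))
    stop_fescycle("bad_config", "crank_weights must be three positive numbers")
  if (!is.numeric(grid_step) || grid_step <= 0 || grid_step > 15)
    stop_fescycle("bad_config", "grid_step must be in (0, 15] degrees")
  structure(list(epsilon = epsilon, epsilon_frac = epsilon_frac,
                 crank_weights = as.numeric(crank_weights),
                 grid_step = grid_step, overlap_policy = overlap_policy),
            class = "pattern_config")
}

# region {q : f(q) > eps} with boundaries refined by bisection; f must be
# vectorised over degrees and periodic
threshold_region <- function(f, eps, grid_step, refine_tol = 1e-4) {
  qs <- seq(0, 360 - grid_step, by = grid_step)
  g <- f(qs) - eps
  on <- g > 0
  if (all(on)) return(full_circle())
  if (!any(on)) return(empty_region())
  n <- length(qs)
  nxt <- c(2:n, 1L)
  cross <- which(on != on[nxt])
  bounds <- vapply(cross, function(i) {
    lo <- qs[i]
    hi <- if (i == n) 360 else qs[i + 1L]
    glo <- g[i]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      gm <- f(mid %% 360) - eps
      if ((gm > 0) == (glo > 0)) {
        lo <- mid
        glo <- gm
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }, numeric(1))
  up <- bounds[!on[cross]]    # off -> on: region starts
  down <- bounds[on[cross]]   # on -> off: region ends
  up <- sort(up %% 360)
  down <- sort(down %% 360)
  arcs <- t(vapply(up, function(s) {
    after <- down[down > s]
    e <- if (length(after)) after[1] else down[1]  # wraps if none after
    c(s, e)
  }, numeric(2)))
  region_set(arcs)
}

# evaluate direction-signed torque-transfer ratios; clockwise pedaling uses
# the ratios as derived, counterclockwise negates them (stimulate where the
# target drives the crank in the commanded direction)
signed_transfer <- function(q, geom, direction) {
  tt <- torque_transfer(q, geom)
  sgn <- if (direction == "cw") 1 else -1
  list(hip = sgn * tt$T_hip, knee = sgn * tt$T_knee, ankle = sgn * tt$T_ankle)
}

target_signal <- function(target, geom, direction, weights) {
  force(target); force(geom); force(direction); force(weights)
  function(q) {
    tt <- signed_transfer(q, geom, direction)
    switch(target,
           GM = tt$hip,
           QM = -tt$knee,
           HM = tt$knee,
           PFM = tt$ankle,
           fn = -tt$knee,
           sn = weights[1] * tt$hip + weights[2] * tt$knee +
             weights[3] * tt$ankle,
           stop_fescycle("bad_target", sprintf("unknown target '%s'", target)))
  }
}

resolve_epsilon <- function(target, signal, cfg, grid) {
  sval <- signal(grid)
  smax <- max(sval)
  amax <- max(abs(sval))
  eps <- if (!is.null(cfg$epsilon) && target %in% names(cfg$epsilon))
    unname(cfg$epsilon[[target]]) else cfg$epsilon_frac * amax
  if (eps >= smax || eps >= amax)
    stop_fescycle("epsilon_infeasible",
                  sprintf(paste0("epsilon for target '%s' (%.4g) is not below the ",
                                 "cycle maximum of its signal (%.4g); the region ",
                                 "would be empty"), target, eps, smax))
  eps
}

build_pattern <- function(targets, version, geom, cfg, direction) {
  grid <- seq(0, 360 - cfg$grid_step, by = cfg$grid_step)
  regions <- list()
  eps_used <- numeric(0)
  for (tg in targets) {
    f <- target_signal(tg, geom, direction, cfg$crank_weights)
    eps <- resolve_epsilon(tg, f, cfg, grid)
    regions[[tg]] <- threshold_region(f, eps, cfg$grid_step)
    eps_used[tg] <- eps
  }
  structure(list(version = version, direction = direction, side = "right",
                 regions = regions, epsilon = eps_used, config = cfg,
                 geometry = geom),
            class = "stimulation_pattern")
}

#' Four-muscle stimulation pattern (version A)
#'
#' Thresholds the torque-transfer profiles into switching regions for the
#' gluteal (GM), quadriceps (QM), hamstrings (HM) and plantarflexor (PFM)
#' muscle groups: each muscle is stimulated only where its FES-evoked joint
#' torque drives the crank in the commanded direction with a transfer ratio
#' exceeding its threshold.  For clockwise pedaling the regions are
#' `GM: T_hip > eps`, `QM: -T_knee > eps`, `HM: T_knee > eps`,
#' `PFM: T_ankle > eps`; counterclockwise applies the same inequalities to
#' the negated ratios.
#'
#' @param geom A [bicycle_geometry()].
#' @param cfg A [pattern_config()].
#' @param direction `"cw"` (clockwise-forward) or `"ccw"`.
#' @return A `stimulation_pattern` (version `"A"`, right side) whose
#'   `regions` element maps each muscle group to a [region_set()].
#' @examples
#' pat <- muscle_regions(default_geometry(), pattern_config(), "cw")
#' pat$regions$QM
#' @export
muscle_regions <- function(geom, cfg = pattern_config(),
                           direction = c("cw", "ccw")) {
  stopifnot(inherits(geom, "bicycle_geometry"), inherits(cfg, "pattern_config"))
  direction <- match.arg(direction)
  build_pattern(c("GM", "QM", "HM", "PFM"), "A", geom, cfg, direction)
}

#' Two-nerve stimulation pattern (version B)
#'
#' Femoral-nerve stimulation recruits the knee extensors, so its region is
#' the set where `-T_knee` exceeds its threshold.  Sciatic-nerve stimulation
#' co-contracts the posterior groups, so its region is where the weighted
#' crank ratio `a1*T_hip + a2*T_knee + a3*T_ankle` exceeds its threshold.
#' Because simultaneous femoral and sciatic stimulation would co-contract
#' antagonists, any overlap between the two regions is removed according to
#' the configured `overlap_policy`; the returned regions are disjoint under
#' every policy.
#'
#' @inheritParams muscle_regions
#' @return A `stimulation_pattern` (version `"B"`, right side) with disjoint
#'   `fn` and `sn` regions.
#' @export
nerve_regions <- function(geom, cfg = pattern_config(),
                          direction = c("cw", "ccw")) {
  stopifnot(inherits(geom, "bicycle_geometry"), inherits(cfg, "pattern_config"))
  direction <- match.arg(direction)
  pat <- build_pattern(c("fn", "sn"), "B", geom, cfg, direction)
  split <- resolve_overlap(pat$regions$fn, pat$regions$sn, pat$config$overlap_policy)
  pat$regions$fn <- split$fn
  pat$regions$sn <- split$sn
  pat
}

# circular components as (start, end) with end possibly past 360 for a
# component spanning the 0/360 seam
circular_component_arcs <- function(x) {
  x <- as_region(x)
  n <- nrow(x)
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  m <- unclass(x)
  if (n > 1L && m[1, 1] <= arc_merge_tol && m[n, 2] >= 360 - arc_merge_tol &&
      region_measure(x) < 360 - arc_merge_tol) {
    m <- rbind(m[-c(1, n), , drop = FALSE],
               c(m[n, 1], m[1, 2] + 360))
  }
  m
}

resolve_overlap <- function(fn, sn, policy) {
  overlap <- region_intersect(fn, sn)
  if (region_measure(overlap) == 0) return(list(fn = fn, sn = sn))
  if (policy == "femoral_priority")
    return(list(fn = fn, sn = region_diff(sn, fn)))
  if (policy == "sciatic_priority")
    return(list(fn = region_diff(fn, sn), sn = sn))
  # split_midpoint: each overlap component is cut at its midpoint and each
  # half is kept by the nerve whose exclusive region adjoins it
  fn_keep <- region_diff(fn, sn)
  sn_keep <- region_diff(sn, fn)
  comps <- circular_component_arcs(overlap)
  for (i in seq_len(nrow(comps))) {
    s <- comps[i, 1]
    e <- comps[i, 2]
    mid <- (s + e) / 2
    before <- (s - 1e-6) %% 360
    first_to_fn <- region_contains(fn_keep, before) ||
      !region_contains(sn_keep, before)
    if (first_to_fn) {
      fn_keep <- region_union(fn_keep, region_set(c(s, mid)))
      sn_keep <- region_union(sn_keep, region_set(c(mid, e)))
    } else {
      sn_keep <- region_union(sn_keep, region_set(c(s, mid)))
      fn_keep <- region_union(fn_keep, region_set(c(mid, e)))
    }
  }
  list(fn = fn_keep, sn = sn_keep)
}

#' Mirror a right-leg pattern to the left leg
#'
#' The left crank arm is mounted 180 degrees out of phase with the right, so
#' the left-leg pattern is the right-leg pattern with every region rotated
#' by 180 degrees.  Applying the function twice returns the original
#' pattern.
#'
#' @param p A `stimulation_pattern`.
#' @return The mirrored `stimulation_pattern` with `side` toggled.
#' @export
left_pattern_from_right <- function(p) {
  stopifnot(inherits(p, "stimulation_pattern"))
  p$regions <- lapply(p$regions, region_rotate, delta = 180)
  p$side <- if (p$side == "right") "left" else "right"
  p
}

#' Is a target stimulated at a crank angle?
#'
#' Membership test a closed-loop controller would poll each encoder sample:
#' stimulation to `target` is on exactly when the crank angle lies in its
#' region (half-open arcs: a region's start angle is on, its end angle off).
#'
#' @param p A `stimulation_pattern`.
#' @param target A target name present in the pattern (`GM`, `QM`, `HM`,
#'   `PFM` for version A; `fn`, `sn` for version B).
#' @param q Crank angle(s) in degrees.
#' @return Logical vector along `q`.
#' @export
is_active <- function(p, target, q) {
  stopifnot(inherits(p, "stimulation_pattern"))
  if (!target %in% names(p$regions))
    stop_fescycle("bad_target",
                  sprintf("pattern has no target '%s' (has: %s)", target,
                          paste(names(p$regions), collapse = ", ")))
  region_contains(p$regions[[target]], q)
}

#' Overlap diagnostic between the gluteal and quadriceps regions
#'
#' Relative symmetric difference
#' `measure(GM delta QM) / measure(QM)` for a version A pattern.  A value
#' near zero means the two regions nearly coincide, the observation that
#' motivates collapsing the four-muscle pattern onto two nerves.  Reported
#' as a diagnostic, not asserted: its size depends on the geometry and
#' thresholds.
#'
#' @param p A version A `stimulation_pattern`.
#' @return A single number (fraction; `NA` if the QM region is empty).
#' @export
pattern_overlap_diagnostic <- function(p) {
  stopifnot(inherits(p, "stimulation_pattern"))
  if (p$version != "A")
    stop_fescycle("bad_target", "overlap diagnostic is defined for version A patterns")
  qm <- region_measure(p$regions$QM)
  if (qm == 0) return(NA_real_)
  sym <- region_union(region_diff(p$regions$GM, p$regions$QM),
                      region_diff(p$regions$QM, p$regions$GM))
  region_measure(sym) / qm
}

#' @export
print.stimulation_pattern <- function(x, ...) {
  cat(sprintf("Stimulation pattern, version %s, %s, %s leg\n",
              x$version, x$direction, x$side))
  for (tg in names(x$regions)) {
    r <- x$regions[[tg]]
    arcs <- if (nrow(r) == 0L) "empty"
    else paste(apply(unclass(r), 1,
                     function(a) sprintf("[%.1f, %.1f)", a[1], a[2])),
               collapse = " u ")
    cat(sprintf("  %-4s eps=%.4g  %s\n", tg, x$epsilon[[tg]], arcs))
  }
  invisible(x)
}
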