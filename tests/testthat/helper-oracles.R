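# Independent oracles used across the suite.  Each re-derives the quantity
# it checks by a different route than the implementation: brute-force grid
# membership for arc measures, finite differences for velocity transforms,
# exhaustive search for the covering arc, and a numeric root-finder for the
# chain closure.

test_geom <- function() default_geometry()

# circular difference a - b wrapped to (-180, 180]
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# membership of grid angles in a raw arc matrix (start < end, no wrap);
# vectorised independently of region_contains
grid_member <- function(q, m) {
  res <- rep(FALSE, length(q))
  for (i in seq_len(nrow(m))) res <- res | (q >= m[i, 1] & q < m[i, 2])
  res
}

# arc measure by 0.01-degree grid counting
grid_measure <- function(x, step = 0.01) {
  q <- seq(0, 360 - step, by = step)
  step * sum(grid_member(q, unclass(fescycle::region_set(x))))
}

# measure of an intersection by grid membership
grid_measure_pair <- function(a, b, step = 0.01) {
  q <- seq(0, 360 - step, by = step)
  step * sum(grid_member(q, unclass(fescycle::region_set(a))) &
               grid_member(q, unclass(fescycle::region_set(b))))
}

# confusion measures by grid membership
grid_confusion <- function(model, exp, step = 0.01) {
  q <- seq(0, 360 - step, by = step)
  inm <- grid_member(q, unclass(fescycle::region_set(model)))
  ine <- grid_member(q, unclass(fescycle::region_set(exp)))
  c(tp = step * sum(inm & ine), tn = step * sum(!inm & !ine),
    fp = step * sum(inm & !ine), fn = step * sum(!inm & ine))
}

# random raw arc list (possibly wrapping/overlapping), not normalised
rand_arcs <- function(k = 5) {
  starts <- stats::runif(k, 0, 360)
  widths <- stats::runif(k, 1, 160)
  cbind(starts, starts + widths)
}

# central finite differences of the joint-angle solutions (degrees per
# degree = radians per radian)
fd_transforms <- function(q, geom, h = 1e-4) {
  up <- solve_joint_angles(q + h, geom)
  dn <- solve_joint_angles(q - h, geom)
  data.frame(
    S_a = circ_diff(up$ankle_angle, dn$ankle_angle) / (2 * h),
    S_h = circ_diff(up$hip_angle, dn$hip_angle) / (2 * h),
    S_k = circ_diff(up$knee_angle, dn$knee_angle) / (2 * h)
  )
}

# exhaustive shortest-covering-arc search: every observation-anchored arc
# (all ordered pairs of observed angles) that contains at least
# ceiling(coverage * n) observations, shortest first, ties by larger count
# then smaller start
brute_roa <- function(angles, coverage = 0.95) {
  a <- sort(angles %% 360)
  n <- length(a)
  m <- max(1L, as.integer(ceiling(coverage * n)))
  best <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      width <- (a[j] - a[i]) %% 360
      count <- sum(((a - a[i]) %% 360) <= width + 1e-9)
      if (count < m) next
      if (is.null(best) ||
          width < best["width"] - 1e-9 ||
          (abs(width - best["width"]) <= 1e-9 &&
           (count > best["count"] ||
            (count == best["count"] && a[i] < best["start"])))) {
        best <- c(width = width, count = count, start = a[i])
      }
    }
  }
  best
}

# numeric root-finder for the chain closure at one crank angle: finds
# (hip, knee) angles (degrees) zeroing the residual, seeded from a coarse
# grid scan, refined by Newton iteration on the 2x2 system
numeric_chain_solution <- function(q, geom) {
  res_fun <- function(hk) {
    st <- data.frame(crank_angle = q, hip_angle = hk[1], knee_angle = hk[2],
                     ankle_angle = ankle_angle(q, geom))
    as.numeric(chain_residual(st, geom))
  }
  grid <- expand.grid(h = seq(-180, 175, by = 5), k = seq(-180, 175, by = 5))
  norms <- apply(grid, 1, function(hk) sqrt(sum(res_fun(hk)^2)))
  # keep the non-hyperextended branch: knee flexed behind the thigh
  ok <- grid$k < grid$h
  grid <- grid[ok, ]
  norms <- norms[ok]
  x <- as.numeric(grid[which.min(norms), ])
  for (iter in 1:60) {
    f <- res_fun(x)
    if (sqrt(sum(f^2)) < 1e-12) break
    eps <- 1e-6
    j11 <- (res_fun(x + c(eps, 0)) - f) / eps
    j12 <- (res_fun(x + c(0, eps)) - f) / eps
    J <- cbind(j11, j12)
    x <- x - as.numeric(solve(J, f))
  }
  x
}
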