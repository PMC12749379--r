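# Closed-chain kinematics: joint angles, joint-velocity transforms and
# torque-transfer ratios of the one-degree-of-freedom hindlimb-bicycle loop.
#
# All public interfaces use degrees; internals are radians.  The encoder
# angle q (increasing = clockwise-forward from the right) maps to the
# internal chain parameter u = (180 - (q - crank_zero_offset)) mod 360, so
# the chain is evaluated in the frame in which its closure equations are
# written while the public angle follows the pedaling convention.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

norm_deg <- function(x) x %% 360

# wrap an angle in radians to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

crank_internal <- function(q_deg, geom) {
  deg2rad((180 - (q_deg - geom$crank_zero_offset_deg)) %% 360)
}

# ankle angle (radians) at internal crank parameter u (radians)
ankle_internal <- function(u, geom) {
  -atan2(geom$crank_length * cos(u),
         geom$crank_length * sin(u) + geom$pedal_rod_distance)
}

# point the thigh-shank chain must reach, expressed through the chain
# closure:  l_t sin(q_h) + l_l sin(q_k) = ax,  l_t cos(q_h) + l_l cos(q_k) = ay
chain_target <- function(u, geom) {
  qa <- ankle_internal(u, geom)
  ax <- geom$hip_offset_x +
    geom$ankle_pedal_vertical * sin(qa) -
    geom$ankle_pedal_horizontal * cos(qa) -
    geom$crank_length * sin(u)
  ay <- geom$hip_offset_y +
    geom$ankle_pedal_horizontal * sin(qa) -
    geom$ankle_pedal_vertical * cos(qa) -
    geom$crank_length * cos(u)
  list(ax = ax, ay = ay, qa = qa)
}

#' Ankle angle over the crank cycle
#'
#' Closed-form ankle angle of the pedal linkage, continuous over the full
#' cycle (computed with the two-argument arctangent).  Because the pedal-rod
#' distance exceeds the crank length, the expression is defined at every
#' crank angle.
#'
#' @param q Crank angle(s) in degrees; any real, normalised mod 360.
#' @param geom A [bicycle_geometry()].
#' @return Ankle angle(s) in degrees.
#' @examples
#' ankle_angle(c(90, 270), default_geometry())  # both zero
#' @export
ankle_angle <- function(q, geom) {
  stopifnot(inherits(geom, "bicycle_geometry"))
  rad2deg(ankle_internal(crank_internal(norm_deg(q), geom), geom))
}

#' Solve the closed chain for hip, knee and ankle angles
#'
#' Computes the joint configuration at each crank angle from the closed-form
#' solution of the chain-closure equations: the ankle angle from the pedal
#' linkage, the hip angle from the two-solution arccosine form (keeping the
#' non-hyperextended branch; the other branch corresponds to hip
#' hyperextension and is discarded), and the knee angle from the remaining
#' two closure components via a two-argument arctangent.
#'
#' @param q Crank angle(s) in degrees.
#' @param geom A [bicycle_geometry()].
#' @return A `joint_state` data frame with columns `crank_angle` (normalised
#'   to `[0, 360)`), `hip_angle`, `knee_angle`, `ankle_angle`, all degrees.
#'   The returned angles satisfy the chain closure to well below
#'   `1e-6 * crank_length` (see [chain_residual()]).
#' @examples
#' js <- solve_joint_angles(seq(0, 350, by = 10), default_geometry())
#' max(sqrt(rowSums(chain_residual(js, default_geometry())^2)))
#' @export
solve_joint_angles <- function(q, geom) {
  stopifnot(inherits(geom, "bicycle_geometry"))
  q <- norm_deg(as.numeric(q))
  u <- crank_internal(q, geom)
  tgt <- chain_target(u, geom)
  lt <- geom$thigh_length
  ll <- geom$shank_length
  r2 <- tgt$ax^2 + tgt$ay^2
  # half-angle form of the closure: cos(q_h - alpha) = c / r
  cc <- (r2 + lt^2 - ll^2) / (2 * lt)
  arg <- cc / sqrt(r2)
  if (any(abs(arg) > 1 + 1e-9)) {
    bad <- which(abs(arg) > 1 + 1e-9)[1]
    stop_fescycle("unreachable_pose",
                  sprintf("limb cannot close the chain at crank angle %.3f deg", q[bad]))
  }
  arg <- pmin(1, pmax(-1, arg))
  alpha <- atan2(tgt$ax, tgt$ay)
  # non-hyperextended branch of the hip angle
  qh <- alpha + acos(arg)
  qk <- atan2(tgt$ax - lt * sin(qh), tgt$ay - lt * cos(qh))
  out <- data.frame(
    crank_angle = q,
    hip_angle = rad2deg(wrap_pi(qh)),
    knee_angle = rad2deg(wrap_pi(qk)),
    ankle_angle = rad2deg(tgt$qa)
  )
  class(out) <- c("joint_state", "data.frame")
  out
}

#' Residual of the chain-closure equations
#'
#' Substitutes a joint configuration back into the vector loop of the closed
#' chain and returns the two residual components in millimetres.  The output
#' of [solve_joint_angles()] has residual norm below
#' `1e-6 * crank_length`; a perturbed configuration does not.
#'
#' @param state A `joint_state` data frame (columns `crank_angle`,
#'   `hip_angle`, `knee_angle`, `ankle_angle`, degrees).
#' @param geom A [bicycle_geometry()].
#' @return An `n x 2` matrix of x/y residuals (mm).
#' @export
chain_residual <- function(state, geom) {
  stopifnot(inherits(geom, "bicycle_geometry"),
            all(c("crank_angle", "hip_angle", "knee_angle", "ankle_angle")
                %in% names(state)))
  u <- crank_internal(norm_deg(state$crank_angle), geom)
  qa <- deg2rad(state$ankle_angle)
  qh <- deg2rad(state$hip_angle)
  qk <- deg2rad(state$knee_angle)
  ax <- geom$hip_offset_x +
    geom$ankle_pedal_vertical * sin(qa) -
    geom$ankle_pedal_horizontal * cos(qa) -
    geom$crank_length * sin(u)
  ay <- geom$hip_offset_y +
    geom$ankle_pedal_horizontal * sin(qa) -
    geom$ankle_pedal_vertical * cos(qa) -
    geom$crank_length * cos(u)
  cbind(
    x = geom$thigh_length * sin(qh) + geom$shank_length * sin(qk) - ax,
    y = geom$thigh_length * cos(qh) + geom$shank_length * cos(qk) - ay
  )
}

singularity_tol <- 1e-8

#' Joint-velocity transforms
#'
#' Dimensionless transforms `S_a`, `S_h`, `S_k` relating crank velocity to
#' ankle, hip and knee joint velocities; each equals the derivative of the
#' corresponding joint angle with respect to the crank angle
#' (radian/radian).  `S_a` comes from differentiating the closed-form ankle
#' angle; `S_h` and `S_k` from differentiating the chain closure and solving
#' the resulting linear system, whose determinant vanishes when
#' `sin(knee_angle - hip_angle) = 0`, i.e. at full limb extension.  The
#' bicycle must be configured so that pose is never reached; the functions
#' raise a `fescycle_singular_pose` error within `1e-8` of it.
#'
#' @inheritParams solve_joint_angles
#' @return A data frame with columns `crank_angle`, `S_a`, `S_h`, `S_k`.
#' @export
velocity_transforms <- function(q, geom) {
  stopifnot(inherits(geom, "bicycle_geometry"))
  q <- norm_deg(as.numeric(q))
  js <- solve_joint_angles(q, geom)
  u <- crank_internal(q, geom)
  qa <- deg2rad(js$ankle_angle)
  qh <- deg2rad(js$hip_angle)
  qk <- deg2rad(js$knee_angle)
  lc <- geom$crank_length
  d <- geom$pedal_rod_distance
  lh <- geom$ankle_pedal_horizontal
  lv <- geom$ankle_pedal_vertical
  # derivatives with respect to the internal parameter u
  sa_u <- (lc^2 + d * lc * sin(u)) * cos(qa)^2 / (lc * sin(u) + d)^2
  dax <- sa_u * (lv * cos(qa) + lh * sin(qa)) - lc * cos(u)
  day <- sa_u * (lh * cos(qa) + lv * sin(qa)) + lc * sin(u)
  den <- sin(qk - qh)
  if (any(abs(den) < singularity_tol)) {
    bad <- which(abs(den) < singularity_tol)[1]
    stop_fescycle("singular_pose",
                  sprintf("full limb extension at crank angle %.3f deg", q[bad]))
  }
  sh_u <- (sin(qk) * dax + cos(qk) * day) / (geom$thigh_length * den)
  sk_u <- -(sin(qh) * dax + cos(qh) * day) / (geom$shank_length * den)
  # du/dq = -1: public transforms are derivatives w.r.t. the encoder angle
  data.frame(crank_angle = q, S_a = -sa_u, S_h = -sh_u, S_k = -sk_u)
}

#' Torque-transfer ratios
#'
#' Dimensionless ratios mapping active torque at each joint to resultant
#' torque at the crank, obtained from the joint-velocity transforms by the
#' principle of virtual work:
#' `T_hip = S_h`, `T_knee = -S_h + S_k`, `T_ankle = S_h - S_k + S_a`.
#' Positive values drive the crank clockwise-forward.
#'
#' @inheritParams solve_joint_angles
#' @return A data frame with columns `crank_angle`, `S_a`, `S_h`, `S_k`,
#'   `T_hip`, `T_knee`, `T_ankle`.
#' @examples
#' tt <- torque_transfer(seq(0, 359), default_geometry())
#' # algebraic identity: the three ratios sum to S_h + S_a
#' max(abs(tt$T_hip + tt$T_knee + tt$T_ankle - (tt$S_h + tt$S_a)))
#' @export
torque_transfer <- function(q, geom) {
  s <- velocity_transforms(q, geom)
  s$T_hip <- s$S_h
  s$T_knee <- -s$S_h + s$S_k
  s$T_ankle <- s$S_h - s$S_k + s$S_a
  s
}
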