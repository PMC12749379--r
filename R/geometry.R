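#' Bicycle/limb geometry for the closed kinematic chain
#'
#' Bundles the eight fixed link lengths of the one-degree-of-freedom
#' hindlimb-bicycle chain: thigh and shank segment lengths, crank arm length,
#' the horizontal/vertical offsets between the ankle joint and the pedal
#' joint, the signed horizontal and vertical offsets of the hip relative to
#' the crank axle, and the horizontal distance between the crank axle and the
#' mounting point of the rod that keeps the pedal oriented.  All lengths are
#' in millimetres.
#'
#' The crank-angle convention used throughout the package: the encoder angle
#' `q` lives on `[0, 360)` degrees, increasing `q` is clockwise-forward
#' pedaling as viewed from the animal's right side, and
#' `q = crank_zero_offset_deg` places the pedal at bottom dead centre
#' (directly below the crank axle, farthest from the hip).
#' `crank_zero_offset_deg` lets users with a different encoder zero remap
#' their readings; it defaults to 0.
#'
#' At construction the geometry is checked for reachability: on a 1 degree
#' grid of crank angles the pedal point must lie inside the annulus the
#' thigh-shank chain can reach from the hip.  A violation is a configuration
#' error, raised immediately rather than mid-computation.
#'
#' @param thigh_length Hip-to-knee segment length (mm), `> 0`.
#' @param shank_length Knee-to-ankle segment length (mm), `> 0`.
#' @param crank_length Crank arm length (mm), `> 0`.
#' @param ankle_pedal_horizontal,ankle_pedal_vertical Components of the
#'   ankle-to-pedal offset in the foot frame (mm), `> 0`.
#' @param hip_offset_x Signed horizontal hip position relative to the crank
#'   axle (mm); negative places the hip behind the axle.  The mapping
#'   protocol uses -10, 0 and +10 mm.
#' @param hip_offset_y Vertical distance from crank axle up to the hip (mm),
#'   `> 0`.
#' @param pedal_rod_distance Horizontal distance between the crank axle and
#'   the pedal-rod mounting point (mm); must exceed `crank_length` so the
#'   ankle-angle expression is defined over the whole cycle.
#' @param crank_zero_offset_deg Encoder reading (degrees) at which the pedal
#'   sits at bottom dead centre.
#'
#' @return An object of class `bicycle_geometry` (a named list of the
#'   arguments).
#' @examples
#' geom <- default_geometry()
#' geom
#' shifted <- shift_hip(geom, +1)  # hips 1 cm in front of the crank axle
#' @seealso [default_geometry()], [read_geometry()], [solve_joint_angles()]
#' @export
bicycle_geometry <- function(thigh_length, shank_length, crank_length,
                             ankle_pedal_horizontal, ankle_pedal_vertical,
                             hip_offset_x, hip_offset_y, pedal_rod_distance,
                             crank_zero_offset_deg = 0) {
  geom <- list(
    thigh_length = as.numeric(thigh_length),
    shank_length = as.numeric(shank_length),
    crank_length = as.numeric(crank_length),
    ankle_pedal_horizontal = as.numeric(ankle_pedal_horizontal),
    ankle_pedal_vertical = as.numeric(ankle_pedal_vertical),
    hip_offset_x = as.numeric(hip_offset_x),
    hip_offset_y = as.numeric(hip_offset_y),
    pedal_rod_distance = as.numeric(pedal_rod_distance),
    crank_zero_offset_deg = as.numeric(crank_zero_offset_deg)
  )
  class(geom) <- "bicycle_geometry"
  validate_geometry(geom)
  geom
}

#' Default rat-bicycle geometry
#'
#' A representative geometry for an adult (4 month old) rat on the stationary
#' bicycle: 40 mm thigh and shank, 25 mm crank, a 10 x 5 mm ankle-to-pedal
#' offset, hip centred over and 50 mm above the crank axle, and a 60 mm
#' pedal-rod distance.  These are plausible magnitudes for adult
#' Sprague-Dawley hindlimb segments and a correspondingly scaled crank; they
#' are a documented stand-in, not measured animal data, and every
#' quantitative claim the package makes is parameterised by the geometry.
#' The configuration is reachable over the full crank cycle for hip shifts
#' of up to +/- 10 mm and stays clear of the full-extension singularity.
#'
#' @return A [bicycle_geometry()] object.
#' @export
default_geometry <- function() {
  bicycle_geometry(
    thigh_length = 40, shank_length = 40, crank_length = 25,
    ankle_pedal_horizontal = 10, ankle_pedal_vertical = 5,
    hip_offset_x = 0, hip_offset_y = 50, pedal_rod_distance = 60
  )
}

#' Shift the hip horizontally
#'
#' Convenience wrapper returning a new geometry whose hip is displaced by
#' `shift_cm` centimetres along the travel axis (positive = in front of the
#' crank axle).  Used for the body-position sensitivity scenarios.
#'
#' @param geom A [bicycle_geometry()] object.
#' @param shift_cm Signed shift in centimetres.
#' @return A validated [bicycle_geometry()] object.
#' @export
shift_hip <- function(geom, shift_cm) {
  stopifnot(inherits(geom, "bicycle_geometry"))
  geom$hip_offset_x <- geom$hip_offset_x + 10 * shift_cm
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  pos <- c("thigh_length", "shank_length", "crank_length",
           "ankle_pedal_horizontal", "ankle_pedal_vertical",
           "hip_offset_y", "pedal_rod_distance")
  for (f in c(pos, "hip_offset_x", "crank_zero_offset_deg")) {
    v <- geom[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_fescycle("bad_geometry", sprintf("field '%s' must be a finite scalar", f))
  }
  for (f in pos) {
    if (geom[[f]] <= 0)
      stop_fescycle("bad_geometry", sprintf("field '%s' must be strictly positive", f))
  }
  if (geom$pedal_rod_distance <= geom$crank_length)
    stop_fescycle("bad_geometry",
                  "pedal_rod_distance must exceed crank_length (ankle angle undefined otherwise)")
  # reachability over a 1 degree grid: the pedal point must stay inside the
  # annulus [ |l_t - l_l|, l_t + l_l ] around the hip
  tgt <- chain_target(seq(0, 359) * pi / 180, geom)
  r <- sqrt(tgt$ax^2 + tgt$ay^2)
  lo <- abs(geom$thigh_length - geom$shank_length)
  hi <- geom$thigh_length + geom$shank_length
  tol <- 1e-9 * hi
  if (any(r > hi + tol) || any(r < lo - tol)) {
    bad <- which(r > hi + tol | r < lo - tol)[1]
    stop_fescycle(
      "unreachable_pose",
      sprintf(paste0("geometry cannot close the chain over the full cycle ",
                     "(hip-to-pedal distance %.2f mm vs limb span [%.2f, %.2f] mm)"),
              r[bad], lo, hi))
  }
  invisible(geom)
}

#' @export
print.bicycle_geometry <- function(x, ...) {
  cat("Bicycle/limb geometry (mm):\n")
  cat(sprintf("  thigh %g, shank %g, crank %g\n",
              x$thigh_length, x$shank_length, x$crank_length))
  cat(sprintf("  ankle-pedal offset (h, v) = (%g, %g)\n",
              x$ankle_pedal_horizontal, x$ankle_pedal_vertical))
  cat(sprintf("  hip offset (x, y) = (%g, %g), pedal-rod distance %g\n",
              x$hip_offset_x, x$hip_offset_y, x$pedal_rod_distance))
  if (x$crank_zero_offset_deg != 0)
    cat(sprintf("  crank zero offset %g deg\n", x$crank_zero_offset_deg))
  invisible(x)
}

geometry_keys <- c("thigh_length", "shank_length", "crank_length",
                   "ankle_pedal_horizontal", "ankle_pedal_vertical",
                   "hip_offset_x", "hip_offset_y", "pedal_rod_distance")

#' Read / write a geometry configuration file
#'
#' The on-disk format is a flat TOML-style `key = value` text file holding
#' the eight length keys (millimetres) plus the optional
#' `crank_zero_offset_deg`.  Blank lines and `#` comments are ignored;
#' unknown keys are rejected so typos fail loudly.
#'
#' @param path File path.
#' @return `read_geometry()` returns a [bicycle_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".toml")
#' write_geometry(default_geometry(), f)
#' identical(read_geometry(f), default_geometry())
#' @export
read_geometry <- function(path) {
  if (!file.exists(path))
    stop_fescycle("bad_config", sprintf("geometry file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop_fescycle("bad_config", sprintf("malformed geometry line: '%s'", bad[1]))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 3L)))
  allowed <- c(geometry_keys, "crank_zero_offset_deg")
  if (any(!keys %in% allowed))
    stop_fescycle("bad_config",
                  sprintf("unknown geometry key '%s'", setdiff(keys, allowed)[1]))
  if (anyNA(vals))
    stop_fescycle("bad_config", "non-numeric geometry value")
  if (anyDuplicated(keys))
    stop_fescycle("bad_config", "duplicated geometry key")
  missing <- setdiff(geometry_keys, keys)
  if (length(missing))
    stop_fescycle("bad_config",
                  sprintf("geometry file lacks key(s): %s", paste(missing, collapse = ", ")))
  args <- as.list(vals)
  names(args) <- keys
  do.call(bicycle_geometry, args)
}

#' @rdname read_geometry
#' @param geom A [bicycle_geometry()] object to serialise.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "bicycle_geometry"))
  keys <- c(geometry_keys, "crank_zero_offset_deg")
  writeLines(sprintf("%s = %.10g", keys, unlist(geom[keys])), path)
  invisible(path)
}

# classed conditions used across the package
stop_fescycle <- function(class, msg, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("fescycle_", class), "error", "condition"),
    list(message = msg, call = call))
  stop(cond)
}
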