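# Seeded synthetic stimulation-trial generator emulating the nerve-mapping
# protocol: start angles on a 15 degree grid, repeated stimulations in
# randomised order, two stimulus frequencies, hip shifts of +/- 1 cm, and a
# 10 degree crank-deviation motion threshold.

#' Configuration for the synthetic-trial generator
#'
#' Ground-truth regions say where stimulation really produces motion; the
#' generator draws motion stochastically around them.  A trial whose start
#' angle is inside the truth region produces motion with probability
#' `inside_motion_prob` (multiplied by `low_freq_attenuation` away from
#' 100 Hz); one outside produces motion with probability
#' `outside_motion_prob`.  A motion trial's deviation is
#' `deviation_scale_deg` times the normalised torque-transfer magnitude at
#' the start angle plus Gaussian noise, floored at the 10 degree motion
#' threshold and signed by the commanded direction; a no-motion trial gets
#' sub-threshold jitter.  The generator has no fatigue model (the protocol's
#' 60 s rests are carried as inert metadata) and fixes the stimulus operating
#' point at 125 us pulse width and 4 mA amplitude.
#'
#' @param ground_truth_regions Named list of [region_set()] objects keyed
#'   `"<nerve>_<direction>"` (e.g. `"fn_cw"`); one entry per (nerve,
#'   direction) to simulate.
#' @param seed Integer seed; mandatory, no implicit clock seeding.
#' @param grid_step_deg Start-angle grid step; must divide 360 (default 15).
#' @param reps_per_angle Stimulations per start angle (default 3).
#' @param freqs_hz Stimulus frequencies tested; first entry is the primary
#'   100 Hz used for RoA estimation, remaining entries stand for the other
#'   frequencies in the protocol (default `c(100, 40)`).
#' @param hip_shifts_cm Lateral hip positions tested (default `c(-1, 0, 1)`).
#' @param deviation_scale_deg Expected deviation (degrees) at a crank angle
#'   where the normalised torque-transfer magnitude is 1 (default 120).
#' @param noise_sd_deg SD of the Gaussian deviation noise (default 8).
#' @param inside_motion_prob P(motion) inside truth at 100 Hz (default
#'   0.95).
#' @param outside_motion_prob P(motion) outside truth (default 0.02).
#' @param low_freq_attenuation Multiplier on `inside_motion_prob` away from
#'   100 Hz (default 0.5).
#' @param condition_plan Optional data frame with columns `direction`,
#'   `hip_shift_cm`, `reps`, `freqs` (comma-separated Hz) describing one
#'   block per (direction, shift); when `NULL`, a uniform plan is built from
#'   `hip_shifts_cm`, `reps_per_angle` and `freqs_hz` for every direction
#'   present in the truth keys.
#' @return An object of class `trial_generator_config`.
#' @seealso [default_study_design()], [generate_trials()]
#' @export
trial_generator_config <- function(ground_truth_regions, seed,
                                   grid_step_deg = 15, reps_per_angle = 3,
                                   freqs_hz = c(100, 40),
                                   hip_shifts_cm = c(-1, 0, 1),
                                   deviation_scale_deg = 120,
                                   noise_sd_deg = 8,
                                   inside_motion_prob = 0.95,
                                   outside_motion_prob = 0.02,
                                   low_freq_attenuation = 0.5,
                                   condition_plan = NULL) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop_fescycle("bad_config", "an explicit integer seed is required")
  if (is.null(names(ground_truth_regions)) ||
      !all(grepl("^(fn|sn)_(cw|ccw)$", names(ground_truth_regions))))
    stop_fescycle("bad_config",
                  "ground_truth_regions must be named '<nerve>_<direction>', e.g. 'fn_cw'")
  ground_truth_regions <- lapply(ground_truth_regions, as_region)
  if (any(vapply(ground_truth_regions, region_measure, numeric(1)) == 0))
    stop_fescycle("bad_config", "ground-truth regions must be nonempty")
  if (360 %% grid_step_deg != 0)
    stop_fescycle("bad_config", "grid_step_deg must divide 360")
  for (p in c(inside_motion_prob, outside_motion_prob, low_freq_attenuation))
    if (!is.finite(p) || p < 0 || p > 1)
      stop_fescycle("bad_config", "probabilities must lie in [0, 1]")
  if (reps_per_angle < 1 || deviation_scale_deg <= 0 || noise_sd_deg < 0)
    stop_fescycle("bad_config", "bad reps/deviation/noise setting")
  if (!is.null(condition_plan)) {
    need <- c("direction", "hip_shift_cm", "reps", "freqs")
    if (!all(need %in% names(condition_plan)))
      stop_fescycle("bad_config",
                    "condition_plan needs columns direction, hip_shift_cm, reps, freqs")
  }
  structure(list(ground_truth_regions = ground_truth_regions,
                 grid_step_deg = grid_step_deg,
                 reps_per_angle = as.integer(reps_per_angle),
                 freqs_hz = as.numeric(freqs_hz),
                 hip_shifts_cm = as.numeric(hip_shifts_cm),
                 deviation_scale_deg = deviation_scale_deg,
                 noise_sd_deg = noise_sd_deg,
                 inside_motion_prob = inside_motion_prob,
                 outside_motion_prob = outside_motion_prob,
                 low_freq_attenuation = low_freq_attenuation,
                 seed = as.integer(seed),
                 condition_plan = condition_plan),
            class = "trial_generator_config")
}

plan_of <- function(cfg) {
  if (!is.null(cfg$condition_plan)) return(cfg$condition_plan)
  dirs <- unique(sub("^(fn|sn)_", "", names(cfg$ground_truth_regions)))
  expand.grid(direction = dirs, hip_shift_cm = cfg$hip_shifts_cm,
              stringsAsFactors = FALSE) |>
    transform(reps = cfg$reps_per_angle,
              freqs = paste(cfg$freqs_hz, collapse = ","))
}

#' Expected number of generated trials
#'
#' Closed-form row count of a generator configuration:
#' `sum over plan blocks of n_nerves x n_angles x reps x n_freqs`.
#'
#' @param cfg A [trial_generator_config()].
#' @return An integer.
#' @export
expected_trial_count <- function(cfg) {
  stopifnot(inherits(cfg, "trial_generator_config"))
  plan <- plan_of(cfg)
  n_angles <- 360 %/% cfg$grid_step_deg
  total <- 0L
  for (i in seq_len(nrow(plan))) {
    nerves <- sum(grepl(paste0("_", plan$direction[i], "$"),
                        names(cfg$ground_truth_regions)))
    nf <- length(strsplit(as.character(plan$freqs[i]), ",")[[1]])
    total <- total + nerves * n_angles * plan$reps[i] * nf
  }
  as.integer(total)
}

#' Study design emulating the reference mapping campaign
#'
#' Builds a generator configuration whose ground truth is the two-nerve
#' model pattern itself (both directions) and whose condition mix echoes the
#' real campaign: the centred hip position carries most trials (both
#' directions, three repetitions per angle at both frequencies), while the
#' backward and forward shifts are smaller clockwise-only blocks.  The
#' expected row count is 720, within ten percent of the 743 trials of the
#' campaign it emulates; this is an emulation of the protocol's shape, not a
#' reconstruction of the animal data.
#'
#' @param geom A [bicycle_geometry()]; ground truth uses the centred
#'   geometry.
#' @param cfg A [pattern_config()] used to build the truth regions.
#' @param seed Integer seed for the generator.
#' @return A [trial_generator_config()].
#' @export
default_study_design <- function(geom = default_geometry(),
                                 cfg = pattern_config(), seed = 1L) {
  cwp <- nerve_regions(geom, cfg, "cw")
  ccwp <- nerve_regions(geom, cfg, "ccw")
  truth <- list(fn_cw = cwp$regions$fn, sn_cw = cwp$regions$sn,
                fn_ccw = ccwp$regions$fn, sn_ccw = ccwp$regions$sn)
  plan <- data.frame(
    direction = c("cw", "ccw", "cw", "cw"),
    hip_shift_cm = c(0, 0, -1, 1),
    reps = c(3L, 3L, 1L, 1L),
    freqs = c("100,40", "100,40", "100,40", "100"),
    stringsAsFactors = FALSE
  )
  trial_generator_config(ground_truth_regions = truth, seed = seed,
                         condition_plan = plan)
}

#' Generate a synthetic stimulation-trial table
#'
#' Simulates the mapping protocol under a [trial_generator_config()]: every
#' (condition block, nerve, grid angle, repetition, frequency) combination
#' yields one trial whose signed crank deviation is drawn as described in
#' the configuration help.  Rows are emitted in a seeded random order (the
#' protocol randomises start angles) and assigned to nine sessions.  The
#' same seed reproduces the table byte for byte.
#'
#' The deviation magnitude is tied to the torque-transfer profile: inside
#' the truth region the expected deviation is proportional to the relevant
#' normalised ratio at the start angle (knee ratio for the femoral nerve,
#' combined crank ratio for the sciatic), evaluated with the block's
#' hip-shifted geometry, so larger modelled leverage produces larger
#' simulated rotations.
#'
#' @param cfg A [trial_generator_config()].
#' @param geom The centred [bicycle_geometry()]; per-block hip shifts are
#'   applied on top of it.
#' @return A list with `trials` (data frame in [read_trials()] layout) and
#'   `manifest` (list with the seed, the truth regions as arc matrices, the
#'   condition plan and per-condition row counts).
#' @export
generate_trials <- function(cfg, geom = default_geometry()) {
  stopifnot(inherits(cfg, "trial_generator_config"),
            inherits(geom, "bicycle_geometry"))
  plan <- plan_of(cfg)
  angles <- seq(0, 360 - cfg$grid_step_deg, by = cfg$grid_step_deg)
  fine <- seq(0, 359.5, by = 0.5)
  rows <- withr::with_seed(cfg$seed, {
    blocks <- list()
    for (b in seq_len(nrow(plan))) {
      dirn <- plan$direction[b]
      shift <- plan$hip_shift_cm[b]
      freqs <- as.numeric(strsplit(as.character(plan$freqs[b]), ",")[[1]])
      g_b <- shift_hip(geom, shift)
      nerves <- sub("_.*$", "",
                    grep(paste0("_", dirn, "$"),
                         names(cfg$ground_truth_regions), value = TRUE))
      for (nerve in nerves) {
        truth <- cfg$ground_truth_regions[[paste(nerve, dirn, sep = "_")]]
        sig <- target_signal(nerve, g_b, dirn, c(1, 1, 1))
        norm <- max(abs(sig(fine)))
        tbar <- pmax(sig(angles), 0) / norm
        grid <- expand.grid(start_angle_deg = angles,
                            rep = seq_len(plan$reps[b]),
                            freq_hz = freqs)
        inside <- region_contains(truth, grid$start_angle_deg)
        p <- ifelse(inside,
                    cfg$inside_motion_prob *
                      ifelse(grid$freq_hz == 100, 1, cfg$low_freq_attenuation),
                    cfg$outside_motion_prob)
        motion <- stats::runif(nrow(grid)) < p
        mag <- cfg$deviation_scale_deg *
          tbar[match(grid$start_angle_deg, angles)] +
          stats::rnorm(nrow(grid), 0, cfg$noise_sd_deg)
        mag <- pmax(mag, 10)
        jitter <- stats::runif(nrow(grid), -10, 10)
        dev <- ifelse(motion, mag, jitter)
        dev <- ifelse(motion & dirn == "ccw", -dev, dev)
        blocks[[length(blocks) + 1L]] <- data.frame(
          nerve = nerve, direction = dirn, hip_shift_cm = shift,
          start_angle_deg = grid$start_angle_deg, freq_hz = grid$freq_hz,
          pulse_width_us = 125, amplitude_ma = 4,
          rest_after_s = 60,
          deviation_deg = round(dev, 4)
        )
      }
    }
    out <- do.call(rbind, blocks)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    out$trial_id <- seq_len(nrow(out))
    out$session_id <- as.integer(cut(seq_len(nrow(out)), breaks = 9,
                                     labels = FALSE))
    out
  })
  rownames(rows) <- NULL
  rows <- rows[, c("trial_id", "session_id", "nerve", "direction",
                   "hip_shift_cm", "start_angle_deg", "freq_hz",
                   "pulse_width_us", "amplitude_ma", "rest_after_s",
                   "deviation_deg")]
  counts <- as.data.frame(table(nerve = rows$nerve, direction = rows$direction,
                                hip_shift_cm = rows$hip_shift_cm))
  counts <- counts[counts$Freq > 0, ]
  rownames(counts) <- NULL
  manifest <- list(
    seed = cfg$seed,
    truth_regions = lapply(cfg$ground_truth_regions,
                           function(r) unclass(as_region(r))[, , drop = FALSE]),
    condition_plan = plan,
    condition_counts = counts,
    n_trials = nrow(rows)
  )
  list(trials = rows, manifest = manifest)
}
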