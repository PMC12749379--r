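# End-to-end pipeline steps: build and serialise patterns, simulate trials,
# estimate RoAs, score model-vs-experiment agreement and report the
# condition table with its summary.  Each run_* function is the engine
# behind one CLI subcommand; all write machine-readable provenance.

#' Serialise / deserialise a stimulation pattern
#'
#' One JSON document per (version, direction, side): metadata, the
#' thresholds used, and one normalised region document per target (degrees,
#' 4 decimal places).
#'
#' @param p A `stimulation_pattern`.
#' @param path File path.
#' @return `write_pattern_json()` returns `path` invisibly;
#'   `read_pattern_json()` a `stimulation_pattern` (without the originating
#'   geometry/config attached).
#' @export
write_pattern_json <- function(p, path) {
  stopifnot(inherits(p, "stimulation_pattern"))
  doc <- list(
    version = p$version, direction = p$direction, side = p$side,
    epsilon = as.list(p$epsilon),
    regions = lapply(p$regions, function(r) {
      r <- as_region(r)
      lapply(seq_len(nrow(r)), function(i) round(as.numeric(r[i, ]), 4))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pattern_json
#' @export
read_pattern_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  regions <- lapply(doc$regions, function(arcs) {
    if (!length(arcs)) return(empty_region())
    region_set(do.call(rbind, lapply(arcs, as.numeric)))
  })
  structure(list(version = doc$version, direction = doc$direction,
                 side = doc$side, regions = regions,
                 epsilon = unlist(doc$epsilon), config = NULL,
                 geometry = NULL),
            class = "stimulation_pattern")
}

log_err <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}

write_provenance <- function(out_dir, what, seed = NULL, params = list()) {
  cfg_json <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  rec <- list(
    step = what,
    package_version = as.character(utils::packageVersion("fescycle")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    params = params
  )
  unlink(tmp)
  jsonlite::write_json(rec, file.path(out_dir, paste0("provenance_", what, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(rec)
}

#' Build and export stimulation patterns
#'
#' Builds the requested pattern versions and directions for one or both
#' sides and writes one JSON document each
#' (`pattern_<version>_<direction>_<side>.json`) under `out_dir`, logging
#' the threshold feasibility margin for every target to standard error.
#'
#' @param geom A [bicycle_geometry()] (or a geometry file path).
#' @param cfg A [pattern_config()].
#' @param versions Subset of `c("A", "B")`.
#' @param directions Subset of `c("cw", "ccw")`.
#' @param sides Subset of `c("right", "left")`; left patterns are the right
#'   patterns rotated by 180 degrees.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named list of patterns written.
#' @export
run_pattern <- function(geom = default_geometry(), cfg = pattern_config(),
                        versions = c("A", "B"), directions = c("cw", "ccw"),
                        sides = "right", out_dir = ".") {
  if (is.character(geom)) geom <- read_geometry(geom)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pats <- list()
  for (v in versions) {
    for (d in directions) {
      p <- if (v == "A") muscle_regions(geom, cfg, d) else nerve_regions(geom, cfg, d)
      grid <- seq(0, 359.9, by = 0.1)
      for (tg in names(p$regions)) {
        sig <- target_signal(tg, geom, d, cfg$crank_weights)
        log_err("pattern %s/%s: target %s eps=%.4g, feasibility margin %.4g",
                v, d, tg, p$epsilon[[tg]], max(sig(grid)) - p$epsilon[[tg]])
      }
      for (s in sides) {
        ps <- if (s == "right") p else left_pattern_from_right(p)
        key <- sprintf("pattern_%s_%s_%s", v, d, s)
        write_pattern_json(ps, file.path(out_dir, paste0(key, ".json")))
        pats[[key]] <- ps
      }
    }
  }
  write_provenance(out_dir, "pattern",
                   params = list(geometry = unclass(geom),
                                 epsilon_frac = cfg$epsilon_frac,
                                 crank_weights = cfg$crank_weights,
                                 overlap_policy = cfg$overlap_policy))
  invisible(pats)
}

#' Simulate a trial campaign and write it to disk
#'
#' Runs [generate_trials()] under the default study design (or a supplied
#' configuration), writing `trials.csv`, `manifest.json` and a provenance
#' record under `out_dir`.
#'
#' @param seed Integer seed (required).
#' @param geom A [bicycle_geometry()].
#' @param design Optional [trial_generator_config()]; default
#'   [default_study_design()] with `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, the list returned by [generate_trials()].
#' @export
run_simulate <- function(seed, geom = default_geometry(), design = NULL,
                         out_dir = ".") {
  if (is.null(design)) design <- default_study_design(geom, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_trials(design, geom)
  write_trials(sim$trials, file.path(out_dir, "trials.csv"))
  jsonlite::write_json(sim$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_provenance(out_dir, "simulate", seed = design$seed,
                   params = list(n_trials = nrow(sim$trials),
                                 plan = sim$manifest$condition_plan))
  log_err("simulate: %d trials across %d conditions",
          nrow(sim$trials), nrow(sim$manifest$condition_counts))
  invisible(sim)
}

#' Estimate experimental RoAs per condition
#'
#' Splits the trial table into (nerve, direction, hip shift) conditions,
#' applies the trial filter (primary frequency, 10 degree motion rule) and
#' estimates one RoA per condition with at least one motion-positive trial.
#'
#' @param trials Trial data frame or CSV path.
#' @param freq_hz,min_dev_deg Passed to [filter_trials()].
#' @param coverage,pad_deg Passed to [estimate_roa()].
#' @param out_dir Optional directory; when given, one region JSON per
#'   condition is written.
#' @return A list of `roa_estimate` objects named
#'   `"<nerve>_<direction>_shift<shift>"`.
#' @export
run_estimate_roa <- function(trials, freq_hz = 100, min_dev_deg = 10,
                             coverage = 0.95, pad_deg = 7.5, out_dir = NULL) {
  if (is.character(trials)) trials <- read_trials(trials)
  conds <- unique(trials[, c("nerve", "direction", "hip_shift_cm")])
  conds <- conds[order(conds$direction, conds$hip_shift_cm, conds$nerve), ]
  out <- list()
  for (i in seq_len(nrow(conds))) {
    sub <- filter_trials(trials, freq_hz = freq_hz, min_dev_deg = min_dev_deg,
                         nerve = conds$nerve[i], direction = conds$direction[i],
                         hip_shift = conds$hip_shift_cm[i])
    ang <- sub$start_angle_deg[sub$motion_observed]
    if (!length(ang)) {
      log_err("estimate-roa: no motion trials for %s/%s shift %g; skipped",
              conds$nerve[i], conds$direction[i], conds$hip_shift_cm[i])
      next
    }
    key <- sprintf("%s_%s_shift%+g", conds$nerve[i], conds$direction[i],
                   conds$hip_shift_cm[i])
    est <- estimate_roa(ang, coverage = coverage, pad_deg = pad_deg)
    out[[key]] <- est
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_region_json(est$region, file.path(out_dir, paste0("roa_", key, ".json")),
                        target = conds$nerve[i],
                        direction = conds$direction[i])
    }
  }
  out
}

#' Score model-versus-experiment agreement per condition
#'
#' The full validation chain for a trial table: per (nerve, direction, hip
#' shift) condition, estimate the experimental RoA, build the model region
#' from the condition's hip-shifted geometry, compute the angular confusion
#' measures and the four agreement ratios.
#'
#' @param trials Trial data frame or CSV path.
#' @param geom Centred [bicycle_geometry()]; shifted per condition.
#' @param cfg [pattern_config()] for the model regions.
#' @param model_regions Optional named list of [region_set()] keyed
#'   `"<nerve>_<direction>"` to use as the model instead of building
#'   patterns (e.g. a truth manifest for parameter-recovery checks).
#' @inheritParams run_estimate_roa
#' @return A data frame with one row per condition: labels, confusion
#'   measures (degrees) and `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
run_validate <- function(trials, geom = default_geometry(),
                         cfg = pattern_config(), model_regions = NULL,
                         freq_hz = 100, min_dev_deg = 10, coverage = 0.95,
                         pad_deg = 7.5) {
  if (is.character(trials)) trials <- read_trials(trials)
  ests <- run_estimate_roa(trials, freq_hz = freq_hz,
                           min_dev_deg = min_dev_deg, coverage = coverage,
                           pad_deg = pad_deg)
  pattern_cache <- list()
  rows <- lapply(names(ests), function(key) {
    parts <- regmatches(key, regexec("^(fn|sn)_(cw|ccw)_shift([+-]?[0-9.]+)$", key))[[1]]
    nerve <- parts[2]; dirn <- parts[3]; shift <- as.numeric(parts[4])
    model <- if (!is.null(model_regions)) {
      model_regions[[paste(nerve, dirn, sep = "_")]]
    } else {
      ck <- sprintf("%s_%g", dirn, shift)
      if (is.null(pattern_cache[[ck]]))
        pattern_cache[[ck]] <<- nerve_regions(shift_hip(geom, shift), cfg, dirn)
      pattern_cache[[ck]]$regions[[nerve]]
    }
    met <- agreement_ratios(roa_confusion(model, ests[[key]]$region))
    data.frame(nerve = nerve, direction = dirn, hip_shift_cm = shift,
               n_motion_trials = ests[[key]]$n_trials_used,
               tp_deg = met$tp_deg, tn_deg = met$tn_deg,
               fp_deg = met$fp_deg, fn_deg = met$fn_deg,
               sensitivity = met$sensitivity, specificity = met$specificity,
               ppv = met$ppv, npv = met$npv)
  })
  do.call(rbind, rows)
}

#' Aggregate a metrics table into the condition-by-metric report
#'
#' Wraps [aggregate_metrics()] around a per-condition metrics table (data
#' frame or CSV path) and optionally writes a report CSV: one row per
#' condition plus one summary row per metric (mean, sample SD, range).
#'
#' @param metrics Data frame from [run_validate()] or a CSV path.
#' @param out_csv Optional output CSV path.
#' @return The `metrics_summary` object.
#' @export
run_report <- function(metrics, out_csv = NULL) {
  if (is.character(metrics)) metrics <- utils::read.csv(metrics)
  agg <- aggregate_metrics(metrics)
  if (!is.null(out_csv)) {
    utils::write.csv(metrics, out_csv, row.names = FALSE)
    utils::write.csv(agg$summary, sub("\\.csv$", "_summary.csv", out_csv),
                     row.names = FALSE)
  }
  agg
}
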