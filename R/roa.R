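# Region-of-activity estimation from stimulation trials and model-versus-
# experiment agreement scoring on angular measures.

trial_columns <- c("trial_id", "session_id", "nerve", "direction",
                   "hip_shift_cm", "start_angle_deg", "freq_hz",
                   "pulse_width_us", "amplitude_ma", "deviation_deg")

#' Filter stimulation trials and flag motion
#'
#' Applies the trial-selection rule used for RoA estimation: keep trials at
#' the requested stimulus frequency (the 100 Hz trials give the most robust
#' contractions) and matching condition keys, and derive the
#' `motion_observed` flag: a trial counts as motion only when the crank
#' deviated by at least `min_dev_deg` degrees *in the commanded direction*
#' (positive deviations are clockwise, so clockwise trials need
#' `deviation >= min_dev_deg` and counterclockwise trials
#' `deviation <= -min_dev_deg`; a 9.9 degree deviation is not motion).
#'
#' @param trials A trial data frame (see [generate_trials()] or
#'   [read_trials()]).
#' @param freq_hz Stimulus frequency to keep (Hz); `NULL` keeps all.
#' @param min_dev_deg Motion threshold in degrees (default 10).
#' @param nerve,direction,hip_shift Optional condition keys (`"fn"`/`"sn"`,
#'   `"cw"`/`"ccw"`, shift in cm); `NULL` keeps all.
#' @return The matching subset with a logical `motion_observed` column.
#'   An empty result triggers a warning, not an error.
#' @export
filter_trials <- function(trials, freq_hz = 100, min_dev_deg = 10,
                          nerve = NULL, direction = NULL, hip_shift = NULL) {
  missing_cols <- setdiff(c("nerve", "direction", "hip_shift_cm",
                            "start_angle_deg", "freq_hz", "deviation_deg"),
                          names(trials))
  if (length(missing_cols))
    stop_fescycle("bad_trials",
                  sprintf("trial table lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  keep <- rep(TRUE, nrow(trials))
  if (!is.null(freq_hz)) keep <- keep & trials$freq_hz == freq_hz
  if (!is.null(nerve)) keep <- keep & trials$nerve == nerve
  if (!is.null(direction)) keep <- keep & trials$direction == direction
  if (!is.null(hip_shift)) keep <- keep & trials$hip_shift_cm == hip_shift
  out <- trials[keep, , drop = FALSE]
  out$motion_observed <- ifelse(out$direction == "cw",
                                out$deviation_deg >= min_dev_deg,
                                out$deviation_deg <= -min_dev_deg)
  if (nrow(out) == 0L)
    warning("no trials match the requested condition", call. = FALSE)
  rownames(out) <- NULL
  out
}

#' Estimate a region of activity from motion-positive start angles
#'
#' The experimental RoA is the shortest contiguous arc of the crank circle
#' that captures at least `coverage` of the start angles at which
#' stimulation produced motion, expanded by `pad_deg` on each end.  The
#' search is anchored on the observed angles (every optimal arc starts at an
#' observation); ties in arc length are broken by larger contained count,
#' then by smallest start angle.  The default padding of 7.5 degrees (half
#' the 15 degree acquisition grid) makes a single observed grid angle
#' contribute one full grid cell; set `pad_deg = 0` for raw arcs.
#'
#' @param motion_angles Start angles (degrees) of motion-positive trials;
#'   must be non-empty (a `fescycle_no_motion_trials` error otherwise).
#' @param coverage Required fraction of observations captured (default
#'   0.95).
#' @param pad_deg Padding added to each end of the covering arc (degrees).
#' @return An object of class `roa_estimate`: list with `region` (a
#'   contiguous [region_set()]), `arc_start`, `arc_end` (degrees; `arc_end`
#'   may exceed 360 when the arc wraps), `n_trials_used` and
#'   `coverage_achieved`.
#' @examples
#' estimate_roa(rep(30, 5))$region            # [22.5, 37.5)
#' @export
estimate_roa <- function(motion_angles, coverage = 0.95, pad_deg = 7.5) {
  motion_angles <- as.numeric(motion_angles)
  if (length(motion_angles) == 0L || anyNA(motion_angles))
    stop_fescycle("no_motion_trials",
                  "RoA estimation needs at least one motion-positive start angle")
  stopifnot(coverage > 0, coverage <= 1, pad_deg >= 0)
  a <- sort(motion_angles %% 360)
  n <- length(a)
  m <- max(1L, as.integer(ceiling(coverage * n)))
  best <- NULL
  for (i in seq_len(n)) {
    j <- ((i + m - 2L) %% n) + 1L
    width <- (a[j] - a[i]) %% 360
    count <- sum(((a - a[i]) %% 360) <= width + 1e-9)
    # an index window that wraps the whole circle collapses to width 0 at a
    # duplicated anchor; such a candidate does not actually cover m points
    if (count < m) next
    cand <- c(width = width, count = count, start = a[i])
    if (is.null(best) ||
        width < best["width"] - 1e-9 ||
        (abs(width - best["width"]) <= 1e-9 &&
         (count > best["count"] ||
          (count == best["count"] && a[i] < best["start"])))) {
      best <- cand
    }
  }
  start <- unname(best["start"]) - pad_deg
  end <- unname(best["start"] + best["width"]) + pad_deg
  region <- if (end - start >= 360) full_circle() else region_set(c(start, end))
  achieved <- mean(((a - start) %% 360) <= (end - start) + 1e-9)
  if (end - start >= 360) achieved <- 1
  structure(list(region = region, arc_start = start %% 360,
                 arc_end = start %% 360 + (end - start),
                 n_trials_used = n, coverage_achieved = achieved),
            class = "roa_estimate")
}

#' @export
print.roa_estimate <- function(x, ...) {
  cat(sprintf("RoA estimate: [%.2f, %.2f) deg (measure %.2f), %d trials, coverage %.3f\n",
              x$arc_start, x$arc_end, region_measure(x$region),
              x$n_trials_used, x$coverage_achieved))
  invisible(x)
}

#' Angular confusion measures between model and experimental RoAs
#'
#' Taking the experimental RoA as truth and the model RoA as prediction, the
#' circle is partitioned into true-positive (`model & experiment`),
#' true-negative (neither), false-positive (model only) and false-negative
#' (experiment only) arc sets; the four angular measures sum to 360 degrees
#' exactly under the half-open arc convention.
#'
#' @param roa_model,roa_exp [region_set()] objects (raw arcs accepted).
#' @return An object of class `agreement_metrics` with elements `tp_deg`,
#'   `tn_deg`, `fp_deg`, `fn_deg`.
#' @export
roa_confusion <- function(roa_model, roa_exp) {
  m <- as_region(roa_model)
  e <- as_region(roa_exp)
  out <- list(
    tp_deg = region_measure(region_intersect(m, e)),
    tn_deg = region_measure(region_complement(region_union(m, e))),
    fp_deg = region_measure(region_intersect(m, region_complement(e))),
    fn_deg = region_measure(region_intersect(region_complement(m), e))
  )
  class(out) <- "agreement_metrics"
  out
}

#' Agreement ratios from confusion measures
#'
#' Fills in sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive
#' predictive value `TP/(TP+FP)` and negative predictive value
#' `TN/(TN+FN)` from the angular confusion measures.  A ratio with a zero
#' denominator (e.g. PPV for an empty model region) is undefined and
#' reported as `NA`, never silently as 0.
#'
#' @param m An `agreement_metrics` object from [roa_confusion()].
#' @return The same object with `sensitivity`, `specificity`, `ppv`, `npv`
#'   added (fractions in `[0, 1]` or `NA`).
#' @export
agreement_ratios <- function(m) {
  stopifnot(inherits(m, "agreement_metrics"))
  ratio <- function(num, den) if (den <= 0) NA_real_ else num / den
  m$sensitivity <- ratio(m$tp_deg, m$tp_deg + m$fn_deg)
  m$specificity <- ratio(m$tn_deg, m$tn_deg + m$fp_deg)
  m$ppv <- ratio(m$tp_deg, m$tp_deg + m$fp_deg)
  m$npv <- ratio(m$tn_deg, m$tn_deg + m$fn_deg)
  m
}

#' @export
print.agreement_metrics <- function(x, ...) {
  cat(sprintf("TP %.1f  TN %.1f  FP %.1f  FN %.1f (deg)\n",
              x$tp_deg, x$tn_deg, x$fp_deg, x$fn_deg))
  if (!is.null(x$sensitivity))
    cat(sprintf("sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
                x$sensitivity, x$specificity, x$ppv, x$npv))
  invisible(x)
}

metric_names <- c("sensitivity", "specificity", "ppv", "npv")

#' Aggregate agreement metrics across conditions
#'
#' Summarises per-condition agreement ratios the way the validation results
#' are reported: per metric, the arithmetic mean, the sample (n-1) standard
#' deviation and the range over all supplied condition rows.  Undefined
#' (`NA`) ratios are excluded pairwise and counted.
#'
#' @param rows A data frame with one row per condition and columns
#'   `sensitivity`, `specificity`, `ppv`, `npv` (any scale: fractions or
#'   percentages), plus optional condition label columns which are carried
#'   through.
#' @return An object of class `metrics_summary`: list with `table` (the
#'   input) and `summary` (a data frame with columns `metric`, `mean`,
#'   `sd`, `min`, `max`, `n_used`, `n_missing`).
#' @examples
#' sens <- c(72.6, 85.1, 70.6, 73.1, 64.5, 83.1, 91.7, 75.4)
#' agg <- aggregate_metrics(data.frame(sensitivity = sens, specificity = NA,
#'                                     ppv = NA, npv = NA))
#' subset(agg$summary, metric == "sensitivity")
#' @export
aggregate_metrics <- function(rows) {
  rows <- as.data.frame(rows)
  if (nrow(rows) < 2L)
    stop_fescycle("bad_metrics", "aggregation needs at least two condition rows")
  missing_cols <- setdiff(metric_names, names(rows))
  if (length(missing_cols))
    stop_fescycle("bad_metrics",
                  sprintf("metrics table lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  summ <- do.call(rbind, lapply(metric_names, function(nm) {
    v <- rows[[nm]]
    ok <- !is.na(v)
    if (sum(!ok) > 0)
      message(sprintf("aggregate_metrics: %d undefined %s value(s) excluded",
                      sum(!ok), nm))
    v <- v[ok]
    data.frame(metric = nm,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               n_used = length(v), n_missing = sum(!ok))
  }))
  structure(list(table = rows, summary = summ), class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat("Per-condition agreement metrics:\n")
  print(x$table, row.names = FALSE)
  cat("\nSummary (mean +/- sample SD (range)):\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-11s %.4g +/- %.3g (%.4g-%.4g), n=%d%s\n",
                s$metric, s$mean, s$sd, s$min, s$max, s$n_used,
                if (s$n_missing) sprintf(" (%d undefined excluded)", s$n_missing) else ""))
  }
  invisible(x)
}

#' Read / write a stimulation-trial CSV
#'
#' The trial table is a plain CSV with columns `trial_id`, `session_id`,
#' `nerve` (`fn`/`sn`), `direction` (`cw`/`ccw`), `hip_shift_cm`,
#' `start_angle_deg`, `freq_hz`, `pulse_width_us`, `amplitude_ma`,
#' `deviation_deg` (signed degrees, positive = clockwise).  Schema
#' violations are reported with the offending row numbers.
#'
#' @param path File path.
#' @return `read_trials()` returns the validated data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path))
    stop_fescycle("bad_trials", sprintf("trial file '%s' does not exist", path))
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_trials(tr)
}

#' @rdname read_trials
#' @param trials A trial data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(validate_trials(trials), path, row.names = FALSE)
  invisible(path)
}

validate_trials <- function(tr) {
  missing_cols <- setdiff(trial_columns, names(tr))
  if (length(missing_cols))
    stop_fescycle("bad_trials",
                  sprintf("trial table lacks column(s): %s",
                          paste(missing_cols, collapse = ", ")))
  bad_row <- function(ok, what) {
    if (any(!ok))
      stop_fescycle("bad_trials",
                    sprintf("%s in row(s) %s", what,
                            paste(utils::head(which(!ok), 5), collapse = ", ")))
  }
  bad_row(tr$nerve %in% c("fn", "sn"), "nerve must be 'fn' or 'sn'")
  bad_row(tr$direction %in% c("cw", "ccw"), "direction must be 'cw' or 'ccw'")
  for (col in c("hip_shift_cm", "start_angle_deg", "freq_hz", "deviation_deg"))
    bad_row(is.finite(tr[[col]]), sprintf("non-finite %s", col))
  bad_row(tr$start_angle_deg >= 0 & tr$start_angle_deg < 360,
          "start_angle_deg outside [0, 360)")
  tr
}
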