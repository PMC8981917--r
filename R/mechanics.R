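#' Subtract the hydrodynamic drag baseline from a trace
#'
#' The drag force of the grippers moving through the bath, measured by
#' running the protocol without a specimen, is interpolated at each
#' specimen extension and removed from the load.  Time and extension
#' are unchanged.
#'
#' @param trace Specimen [tensile_trace()].
#' @param baseline Baseline trace with `is_baseline = TRUE`.
#' @return The corrected trace (attribute `"drag_subtracted"` set).
#' @export
subtract_drag <- function(trace, baseline) {
  validate_trace(trace); validate_trace(baseline)
  if (!baseline$is_baseline) stop("baseline trace must have is_baseline = TRUE")
  span_tr <- range(trace$extension)
  span_bl <- range(baseline$extension)
  cover <- (min(span_tr[2], span_bl[2]) - max(span_tr[1], span_bl[1])) /
    max(span_tr[2] - span_tr[1], .Machine$double.eps)
  if (cover < 0.9)
    stop(sprintf("baseline extension range covers only %.0f%% of the trace range", 100 * cover))
  bl <- stats::approx(baseline$extension, baseline$load,
                      xout = trace$extension, rule = 2, ties = mean)$y
  out <- trace
  out$load <- trace$load - bl
  attr(out, "ground_truth") <- attr(trace, "ground_truth")
  attr(out, "drag_subtracted") <- TRUE
  out
}

#' Detect tension onset and record the gauge length
#'
#' The specimen is considered in tension at the first sample whose raw
#' (pre-drag-subtraction) load exceeds the threshold; the gauge length
#' is the grip-to-grip distance at that sample.
#'
#' @param trace Raw [tensile_trace()].
#' @param protocol [test_protocol()] supplying the initial grip distance.
#' @param threshold Load threshold in N (default 0.005 N = 5 mN, the
#'   load-cell resolution).
#' @return List with `onset_index` (1-based) and `gauge_length` (mm).
#' @export
detect_tension_onset <- function(trace, protocol, threshold = 0.005) {
  validate_trace(trace)
  stopifnot(inherits(protocol, "test_protocol"))
  if (threshold <= 0) stop("threshold must be positive")
  idx <- which(trace$load > threshold)
  if (length(idx) == 0)
    stop(sprintf("specimen never in tension: no load above %.3f N", threshold))
  i <- idx[1]
  list(onset_index = i,
       gauge_length = protocol$initial_grip_distance + trace$extension[i])
}

#' Elliptical cross-sectional area
#'
#' A0 of a ring limb from its top-view width and side-view height,
#' modelled as an ellipse: `pi * (width/2) * (height/2)`.
#'
#' @param width,height mm, positive (vectorized).
#' @return Area(s) in mm^2.
#' @examples
#' elliptical_area(1, 1)      # pi/4
#' elliptical_area(0.8, 0.6)  # 0.12 * pi
#' @export
elliptical_area <- function(width, height) {
  if (any(width <= 0) || any(height <= 0))
    stop("width and height must be positive")
  pi * (width / 2) * (height / 2)
}

#' Convert a drag-corrected trace to stress-strain
#'
#' Engineering strain is extension change past the tension onset over
#' the gauge length; engineering stress is load over twice the initial
#' cross-sectional area (the ring's two limbs share the load).  True
#' measures assume volume conservation and uniform deformation:
#' `true_strain = log(1 + eng_strain)`,
#' `true_stress = eng_stress * (1 + eng_strain)`.
#'
#' @param trace Drag-corrected [tensile_trace()].
#' @param onset_index 1-based onset sample from [detect_tension_onset()].
#' @param gauge_length mm (> 0).
#' @param a0 Initial cross-sectional area, mm^2 (> 0).
#' @param area_convention `"minimum"` or `"mean"`, recorded for provenance.
#' @return Object of class `stress_strain_curve` with fields
#'   `eng_strain`, `eng_stress`, `true_strain`, `true_stress` (MPa,
#'   since N/mm^2 = MPa), `gauge_length`, `a0`, `area_convention`,
#'   `onset_index`.
#' @export
to_stress_strain <- function(trace, onset_index, gauge_length, a0,
                             area_convention = c("minimum", "mean")) {
  area_convention <- match.arg(area_convention)
  validate_trace(trace)
  if (gauge_length <= 0) stop("gauge_length must be positive")
  if (a0 <= 0) stop("a0 must be positive")
  n <- length(trace$time)
  if (onset_index < 1 || onset_index > n) stop("onset_index outside trace")
  sel <- onset_index:n
  eng_strain <- (trace$extension[sel] - trace$extension[onset_index]) / gauge_length
  eng_stress <- trace$load[sel] / (2 * a0)
  structure(list(eng_strain = eng_strain,
                 eng_stress = eng_stress,
                 true_strain = log(1 + eng_strain),
                 true_stress = eng_stress * (1 + eng_strain),
                 gauge_length = gauge_length, a0 = a0,
                 area_convention = area_convention,
                 onset_index = as.integer(onset_index)),
            class = "stress_strain_curve")
}

# centred moving average with shrinking windows at the edges
moving_average <- function(v, w) {
  w <- as.integer(w)
  if (w <= 1L || length(v) < 2L) return(v)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  i <- seq_along(v)
  lo <- pmax(1L, i - half); hi <- pmin(length(v), i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# pick the stress/strain arrays for a convention
curve_axes <- function(curve, stress_convention = c("engineering", "true")) {
  stress_convention <- match.arg(stress_convention)
  if (stress_convention == "engineering")
    list(strain = curve$eng_strain, stress = curve$eng_stress)
  else
    list(strain = curve$true_strain, stress = curve$true_stress)
}

#' Sliding-window tangent modulus profile
#'
#' For every sample whose following strain window of width
#' `window_strain` fits inside the curve, the ordinary least-squares
#' slope of stress on strain over that window.  The maximum of this
#' profile is the maximum tangent modulus (MTM), the construct's
#' "stiffness".
#'
#' @param curve A [to_stress_strain()] curve.
#' @param window_strain Window width in strain units (default 0.08,
#'   i.e. 8 % strain).
#' @param stress_convention `"engineering"` (default) or `"true"`;
#'   selects both the stress and the strain axis.
#' @param last_index Restrict the curve to samples `1..last_index`
#'   (e.g. the failure index); default the whole curve.
#' @return data.frame with columns `window_start_strain`,
#'   `window_end_strain`, `slope` (MPa), plus start/end sample indices.
#' @export
tangent_modulus_profile <- function(curve, window_strain = 0.08,
                                    stress_convention = c("engineering", "true"),
                                    last_index = NULL) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  ax <- curve_axes(curve, stress_convention)
  n0 <- length(ax$strain)
  if (is.null(last_index)) last_index <- n0
  if (last_index < 2 || last_index > n0) stop("last_index outside curve")
  x <- ax$strain[seq_len(last_index)]
  y <- ax$stress[seq_len(last_index)]
  span <- x[length(x)] - x[1]
  if (span < window_strain)
    stop(sprintf("curve too short: strain span %.4f < window %.4f",
                 span, window_strain))
  # window ends: last sample with strain <= start + window_strain
  ends <- findInterval(x + window_strain, x)
  starts <- which(x + window_strain <= x[length(x)] + 1e-12)
  ends <- pmin(ends[starts], length(x))
  ok <- (ends - starts + 1L) >= 3L
  if (!any(ok)) stop("no window contains at least 3 samples")
  starts <- starts[ok]; ends <- ends[ok]
  # O(1) per-window OLS slopes via zero-padded cumulative sums
  cx <- cumsum(c(0, x)); cy <- cumsum(c(0, y))
  cxx <- cumsum(c(0, x * x)); cxy <- cumsum(c(0, x * y))
  csum <- function(cs, i, j) cs[j + 1L] - cs[i]
  m <- ends - starts + 1L
  sx <- csum(cx, starts, ends); sy <- csum(cy, starts, ends)
  sxx <- csum(cxx, starts, ends); sxy <- csum(cxy, starts, ends)
  slope <- (m * sxy - sx * sy) / (m * sxx - sx * sx)
  data.frame(window_start_strain = x[starts],
             window_end_strain = x[ends],
             start_index = starts, end_index = ends,
             slope = slope)
}

#' Detect the failure event
#'
#' Failure is the first sample whose load (or stress) falls below
#' `(1 - drop_fraction)` times the running maximum of the preceding
#' samples -- the instrument's termination criterion.  If no sample
#' qualifies, the last sample is returned with `failure_detected =
#' FALSE`.
#'
#' @param values Numeric load or stress series (>= 2 samples), or a
#'   `stress_strain_curve` (engineering stress is used).
#' @param drop_fraction Fractional drop (default 0.40).
#' @param min_peak_frac The rule is evaluated only once the running
#'   maximum exceeds this fraction of the series' global maximum
#'   (default 0.1).  A relative drop rule applied to the near-zero
#'   slack/toe load would otherwise trigger on measurement noise; this
#'   offline guard does not alter noise-free traces.
#' @param smooth_n Centred moving-average width (samples) applied to
#'   the series before evaluating the rule (default 1 = none).  On
#'   noisy traces the running maximum is inflated by noise extremes and
#'   the relative rule mis-fires; a short average (about 0.5 s of
#'   samples) restores the intended behaviour while shifting the
#'   detected index by at most half the window.
#' @return List with `failure_index` (1-based) and `failure_detected`.
#' @examples
#' detect_failure(c(10, 50, 100, 58))  # index 4: 58 < 0.6 * 100
#' detect_failure(c(100, 70))          # 30 % drop: not failure
#' @export
detect_failure <- function(values, drop_fraction = 0.40, min_peak_frac = 0.1,
                           smooth_n = 1L) {
  if (inherits(values, "stress_strain_curve")) values <- values$eng_stress
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 samples")
  values <- moving_average(values, smooth_n)
  runmax <- cummax(values)
  prior <- c(-Inf, runmax[-length(values)])
  hit <- which(values < (1 - drop_fraction) * prior &
               prior >= min_peak_frac * max(values))
  if (length(hit) == 0)
    list(failure_index = length(values), failure_detected = FALSE)
  else
    list(failure_index = hit[1], failure_detected = TRUE)
}

#' Summarize a stress-strain curve into the three endpoints
#'
#' UTS is the peak stress at or before the failure sample; MTM is the
#' largest window slope among windows ending at or before the failure
#' sample (ties resolve to the earliest window); failure strain is the
#' strain at the failure sample.  Strain at peak stress is also
#' reported as an alternative failure measure.
#'
#' For noisy traces the raw sample maximum is an upward-biased UTS
#' estimate (extreme-value bias); `peak_smooth_s` applies a centred
#' moving average of that duration to the stress series for the peak
#' readout only (0, the default, keeps the raw maximum).
#'
#' @param curve A [to_stress_strain()] curve.
#' @param profile A [tangent_modulus_profile()] (computed with the same
#'   stress convention).
#' @param failure List from [detect_failure()] (or an integer index).
#' @param stress_convention `"engineering"` (default) or `"true"`.
#' @param peak_smooth_s Moving-average duration (seconds) for the UTS
#'   readout; requires `sampling_rate`.
#' @param sampling_rate Hz, used only to size the smoothing window.
#' @return Object of class `mechanical_summary`: `uts`, `mtm`,
#'   `failure_strain`, `strain_at_uts`, `mtm_window_start_strain`,
#'   `failure_detected`, `stress_convention`, `area_convention`.
#' @export
summarize_mechanics <- function(curve, profile, failure,
                                stress_convention = c("engineering", "true"),
                                peak_smooth_s = 0, sampling_rate = 20) {
  stress_convention <- match.arg(stress_convention)
  stopifnot(inherits(curve, "stress_strain_curve"), is.data.frame(profile))
  if (nrow(profile) == 0) stop("empty tangent-modulus profile")
  if (is.list(failure)) {
    fi <- failure$failure_index; fd <- isTRUE(failure$failure_detected)
  } else {
    fi <- as.integer(failure); fd <- TRUE
  }
  ax <- curve_axes(curve, stress_convention)
  if (fi < 1 || fi > length(ax$strain)) stop("failure index outside curve")

  keep <- profile$end_index <= fi
  if (!any(keep))
    stop("failure occurs before the first full tangent window")
  prof <- profile[keep, , drop = FALSE]
  best <- which(prof$slope == max(prof$slope))[1]   # earliest on ties

  stress <- ax$stress[seq_len(fi)]
  if (peak_smooth_s > 0)
    stress <- moving_average(stress,
                             max(1L, as.integer(round(peak_smooth_s * sampling_rate))))
  iu <- which.max(stress)
  structure(list(uts = stress[iu],
                 mtm = prof$slope[best],
                 failure_strain = ax$strain[fi],
                 strain_at_uts = ax$strain[iu],
                 mtm_window_start_strain = prof$window_start_strain[best],
                 failure_detected = fd,
                 stress_convention = stress_convention,
                 area_convention = curve$area_convention),
            class = "mechanical_summary")
}

#' Analyze one specimen trace end to end
#'
#' Onset detection on the raw load, drag subtraction, stress-strain
#' conversion with the chosen area convention, tangent-modulus profile,
#' failure detection and endpoint summary.
#'
#' @param trace Raw specimen [tensile_trace()].
#' @param baseline Drag baseline trace, or NULL to skip subtraction.
#' @param geometry [specimen_geometry()].
#' @param protocol [test_protocol()].
#' @param area_convention `"minimum"` (default) or `"mean"`.
#' @param stress_convention `"engineering"` (default) or `"true"`.
#' @param window_strain Tangent window width (default 0.08).
#' @param onset_threshold N (default 0.005).
#' @param peak_smooth_s See [summarize_mechanics()].
#' @param failure_smooth_s Moving-average duration (seconds) for the
#'   failure-rule evaluation (default 0.5; see [detect_failure()]).
#' @return One-row data.frame: `specimen_id, uts_mpa, mtm_mpa,
#'   failure_strain, strain_at_uts, failure_detected, a0_mm2,
#'   area_convention, gauge_length_mm, stress_convention`.
#' @export
analyze_trace <- function(trace, baseline, geometry, protocol,
                          area_convention = c("minimum", "mean"),
                          stress_convention = c("engineering", "true"),
                          window_strain = 0.08, onset_threshold = 0.005,
                          peak_smooth_s = 0, failure_smooth_s = 0.5) {
  area_convention <- match.arg(area_convention)
  stress_convention <- match.arg(stress_convention)
  stopifnot(inherits(geometry, "specimen_geometry"))
  onset <- detect_tension_onset(trace, protocol, onset_threshold)
  corrected <- if (is.null(baseline)) trace else subtract_drag(trace, baseline)
  a0 <- if (area_convention == "minimum") geometry$a0_min else geometry$a0_mean
  curve <- to_stress_strain(corrected, onset$onset_index, onset$gauge_length,
                            a0, area_convention)
  fail <- detect_failure(curve, protocol$termination_drop_fraction,
                         smooth_n = max(1L, as.integer(round(
                           failure_smooth_s * protocol$sampling_rate))))
  profile <- tangent_modulus_profile(curve, window_strain, stress_convention)
  smry <- summarize_mechanics(curve, profile, fail, stress_convention,
                              peak_smooth_s = peak_smooth_s,
                              sampling_rate = protocol$sampling_rate)
  data.frame(specimen_id = trace$specimen_id,
             uts_mpa = smry$uts, mtm_mpa = smry$mtm,
             failure_strain = smry$failure_strain,
             strain_at_uts = smry$strain_at_uts,
             failure_detected = smry$failure_detected,
             a0_mm2 = a0, area_convention = area_convention,
             gauge_length_mm = onset$gauge_length,
             stress_convention = stress_convention,
             stringsAsFactors = FALSE)
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat(sprintf("Mechanical summary (%s stress, %s area)\n",
              x$stress_convention, x$area_convention))
  cat(sprintf("  UTS            : %.3f MPa (at strain %.3f)\n", x$uts, x$strain_at_uts))
  cat(sprintf("  MTM            : %.3f MPa (window start strain %.3f)\n",
              x$mtm, x$mtm_window_start_strain))
  cat(sprintf("  failure strain : %.3f (%s)\n", x$failure_strain,
              if (x$failure_detected) "failure detected" else "no failure event"))
  invisible(x)
}

#' @export
print.stress_strain_curve <- function(x, ...) {
  cat(sprintf("Stress-strain curve: %d samples, strain span %.3f, peak eng stress %.3f MPa (A0 = %.4f mm^2, %s)\n",
              length(x$eng_strain), max(x$eng_strain), max(x$eng_stress),
              x$a0, x$area_convention))
  invisible(x)
}
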