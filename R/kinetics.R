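#' Closed-form extrusion-speed and stoichiometry estimators
#'
#' A family of small estimators that convert observable quantities of
#' mitotic chromosome assembly (loop sizes read off P(s) derivatives,
#' helical periods, gap fractions, chromatin-bound protein abundances)
#' into loop-extrusion speeds and per-Mb complex numbers. All functions
#' return full-precision values; use [format_speed()] for display rounding.
#'
#' @name kinetics
NULL

new_speed_estimate <- function(value, units, method, inputs) {
  stopifnot(is.finite(value), value >= 0 || is.na(value))
  structure(
    list(value = value, units = units, method = method, inputs = inputs),
    class = "speed_estimate"
  )
}

#' @export
print.speed_estimate <- function(x, ...) {
  cat(sprintf("<speed_estimate> %s: %.4g %s\n", x$method, x$value, x$units))
  invisible(x)
}

#' Extrusion speed from the size of the first loops
#'
#' Speed inferred from the loop size reached a given number of minutes
#' after loop-extruding condensin is activated, assuming extrusion started
#' from zero-size loops.
#'
#' @param loop_kb loop size in kb reached at time `minutes`.
#' @param minutes elapsed time in minutes (> 0).
#' @return a `speed_estimate` in kb/s.
#' @examples
#' speed_from_first_loops(400, 5)$value  # ~1.33 kb/s
#' @export
speed_from_first_loops <- function(loop_kb, minutes) {
  stopifnot(is.numeric(loop_kb), loop_kb >= 0)
  if (!is.numeric(minutes) || minutes <= 0) stop("minutes must be > 0")
  new_speed_estimate(loop_kb / (60 * minutes), "kb/s", "first_loops",
                     list(loop_kb = loop_kb, minutes = minutes))
}

#' Extrusion speed from loop growth between two time points
#'
#' @param l0_kb,l1_kb loop sizes in kb at the start and end of the interval.
#' @param minutes interval length in minutes (> 0).
#' @return a `speed_estimate` in kb/s; negative growth is clamped to 0 with
#'   a warning.
#' @export
speed_from_loop_growth <- function(l0_kb, l1_kb, minutes) {
  if (!is.numeric(minutes) || minutes <= 0) stop("minutes must be > 0")
  growth <- l1_kb - l0_kb
  if (growth < 0) {
    warning("negative loop growth; returning speed 0")
    growth <- 0
  }
  new_speed_estimate(growth / (60 * minutes), "kb/s", "loop_growth",
                     list(l0_kb = l0_kb, l1_kb = l1_kb, minutes = minutes))
}

#' Extrusion speed from the residual gap fraction
#'
#' In a dense loop array the fraction of chromatin left in gaps between
#' loops decays as `g = exp(-lambda/d)` where `lambda = v * t` is the
#' processivity accrued by time `t` and `d` the extruder spacing.
#' Inverting gives `v = -d * log(g) / t`.
#'
#' @param d_kb extruder separation in kb.
#' @param g gap fraction, strictly inside (0, 1).
#' @param seconds elapsed time in seconds.
#' @return a `speed_estimate` in kb/s.
#' @export
speed_from_gap_fraction <- function(d_kb, g, seconds) {
  stopifnot(d_kb > 0, seconds > 0)
  if (!is.numeric(g) || g <= 0 || g >= 1) stop("g must be in (0, 1)")
  new_speed_estimate(-d_kb * log(g) / seconds, "kb/s", "gap_fraction",
                     list(d_kb = d_kb, g = g, seconds = seconds))
}

#' Extrusion speed from the gap-closing multiplier
#'
#' Closing most gaps of a loop array requires each extruder to reel in
#' `k` times the average loop size (k ~ 4-5 for near-complete coverage).
#'
#' @param l_loop_kb average loop size in kb.
#' @param k multiples of the loop size extruded (> 0).
#' @param seconds elapsed time in seconds.
#' @return a `speed_estimate` in kb/s.
#' @examples
#' speed_from_gap_multiplier(400, 4, 600)$value  # ~2.67 kb/s
#' @export
speed_from_gap_multiplier <- function(l_loop_kb, k, seconds) {
  stopifnot(l_loop_kb >= 0, seconds > 0)
  if (!is.numeric(k) || k <= 0) stop("k must be > 0")
  new_speed_estimate(k * l_loop_kb / seconds, "kb/s", "gap_multiplier",
                     list(l_loop_kb = l_loop_kb, k = k, seconds = seconds))
}

#' Growth rate of the helical period
#'
#' Rate at which the genomic content of one helical turn (the position of
#' the second Hi-C diagonal) grows between two time points.
#'
#' @param p0_Mb,p1_Mb helical period in Mb at the two time points.
#' @param minutes interval in minutes (> 0).
#' @return a `speed_estimate` in kb/s with an extra `kb_per_min` field in
#'   `inputs`.
#' @examples
#' period_growth_rate(4.0, 6.1, 15)$value   # ~2.33 kb/s
#' period_growth_rate(6.6, 16.4, 15)$value  # ~10.9 kb/s
#' @export
period_growth_rate <- function(p0_Mb, p1_Mb, minutes) {
  if (!is.numeric(minutes) || minutes <= 0) stop("minutes must be > 0")
  kb_per_min <- (p1_Mb - p0_Mb) * 1000 / minutes
  new_speed_estimate(max(kb_per_min, 0) / 60, "kb/s", "period_growth",
                     list(p0_Mb = p0_Mb, p1_Mb = p1_Mb, minutes = minutes,
                          kb_per_min = kb_per_min))
}

#' Effective extrusion velocity from loop size and residence time
#'
#' For a dynamically exchanging extruder the mean loop size divided by the
#' chromatin residence time gives the effective (processivity-limited)
#' extrusion velocity.
#'
#' @param loop_kb mean loop size in kb.
#' @param residence_min mean residence time in minutes (> 0).
#' @return a `speed_estimate` in kb/min.
#' @examples
#' effective_velocity(100, 10)$value  # 10 kb/min
#' @export
effective_velocity <- function(loop_kb, residence_min) {
  stopifnot(loop_kb >= 0)
  if (!is.numeric(residence_min) || residence_min <= 0)
    stop("residence_min must be > 0")
  new_speed_estimate(loop_kb / residence_min, "kb/min", "effective_velocity",
                     list(loop_kb = loop_kb, residence_min = residence_min))
}

#' Map a real-time extrusion velocity to an MD-step interval
#'
#' Simulation time is calibrated against the measured Rouse time of a
#' chromatin region: `rouse_md_steps` MD steps correspond to
#' `rouse_minutes` of real time. A loop-extruding factor moving both legs
#' by one bead per step extrudes `kb_per_bead * legs_per_step` kb per
#' 1D step, so the interval between 1D steps in MD steps is
#' `steps_per_minute / events_per_minute`.
#'
#' @param rouse_minutes measured Rouse time in minutes.
#' @param rouse_md_steps simulated Rouse time in MD steps.
#' @param v_kb_per_min extrusion velocity in kb/min.
#' @param kb_per_bead lattice/bead resolution in kb.
#' @param legs_per_step number of legs moved per 1D step (2 = two-sided).
#' @return interval between LEF steps, in MD steps (`Inf` if `v = 0`).
#' @examples
#' md_step_interval(120, 6e6, 10, 1)  # 10000
#' @export
md_step_interval <- function(rouse_minutes, rouse_md_steps, v_kb_per_min,
                             kb_per_bead, legs_per_step = 2) {
  stopifnot(rouse_minutes > 0, rouse_md_steps > 0, kb_per_bead > 0,
            legs_per_step > 0, v_kb_per_min >= 0)
  if (v_kb_per_min == 0) return(Inf)
  steps_per_minute <- rouse_md_steps / rouse_minutes
  events_per_minute <- v_kb_per_min / (kb_per_bead * legs_per_step)
  steps_per_minute / events_per_minute
}

#' Nucleosome-equivalent cube side from chromatin volume density
#'
#' Converts a volume density in Mb per cubic micron into the side of the
#' cube of space available to one nucleosome worth of DNA.
#'
#' @param rho_V_Mb_per_um3 volume density in Mb/um^3.
#' @param bp_per_nucleosome DNA per nucleosome in bp (default 200).
#' @return cube side in nm.
#' @examples
#' nucleosome_cube_side(44)  # ~16.5 nm
#' @export
nucleosome_cube_side <- function(rho_V_Mb_per_um3, bp_per_nucleosome = 200) {
  stopifnot(rho_V_Mb_per_um3 > 0, bp_per_nucleosome > 0)
  # Mb/um^3 -> bp/nm^3: 1 Mb = 1e6 bp, 1 um^3 = 1e9 nm^3
  bp_per_nm3 <- rho_V_Mb_per_um3 * 1e6 / 1e9
  (bp_per_nucleosome / bp_per_nm3)^(1 / 3)
}

#' Chromatin-bound complexes per megabase from an H4 molar ratio
#'
#' Chromatin proteomics reports protein abundances as molar ratios to
#' histone H4; two H4 molecules correspond to one nucleosome, i.e. 180 bp
#' of DNA, so one Mb of chromatin carries 2e6/180 H4 molecules.
#'
#' @param abundance_ratio_to_H4 molar ratio of the complex to histone H4.
#' @return complexes per Mb of DNA.
#' @examples
#' complexes_per_mb(9e-4)  # ~10 per Mb
#' @export
complexes_per_mb <- function(abundance_ratio_to_H4) {
  stopifnot(abundance_ratio_to_H4 >= 0)
  abundance_ratio_to_H4 * 2e6 / 180
}

#' Display rounding for speed estimates
#'
#' Rounds to one decimal in kb/s (or kb/min), matching the conventional
#' reporting precision, while leaving the underlying estimates at full
#' precision.
#'
#' @param x a `speed_estimate` or numeric value.
#' @param digits decimal digits (default 1).
#' @return character scalar.
#' @export
format_speed <- function(x, digits = 1) {
  if (inherits(x, "speed_estimate")) {
    sprintf(paste0("%.", digits, "f %s"), round(x$value, digits), x$units)
  } else {
    sprintf(paste0("%.", digits, "f"), round(x, digits))
  }
}
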