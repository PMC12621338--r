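#' Canonical activity class labels
#'
#' The eight activity-of-daily-living classes recognised by the pipeline, in
#' the fixed order used for class indices, confusion matrices and the softmax
#' output layer.
#'
#' @return Character vector of length 8.
#' @export
adl_classes <- function() {
  c("jogging", "knee_bending", "sitting_down", "standing_up",
    "walking", "standing_still", "stair_ascent", "stair_descent")
}

#' Construct an activity kinematic profile
#'
#' An `activity_profile` holds the per-class knee-flexion kinematics that
#' drive the synthetic dual-IMU generator: the flexion range of motion, the
#' cycle rate, the waveform family, how much of the flexion is expressed as
#' femoral-segment rotation in the world frame, and (for jogging) the
#' footstrike impact amplitude.
#'
#' @param name activity label, one of [adl_classes()].
#' @param rom_min,rom_max flexion range of motion bounds, degrees;
#'   `rom_min < rom_max`.
#' @param rate cycle frequency in Hz; must satisfy `0 < rate <= 2`.
#' @param waveform one of `"periodic"` (raised-cosine oscillation),
#'   `"half_cycle_down"` (single monotone ramp `rom_min -> rom_max`),
#'   `"half_cycle_up"` (ramp `rom_max -> rom_min`), `"quasi_static"`
#'   (low-amplitude oscillation within the range).
#' @param femoral_share fraction in `[0, 1]` of the knee flexion expressed as
#'   femoral rotation; the remainder appears in the tibial segment.
#' @param impact_amplitude accelerometer footstrike transient amplitude,
#'   m/s^2 (0 for all classes except jogging).
#' @param thigh_start,thigh_end thigh inclination (degrees from vertical) at
#'   the start and end of the activity; sit/stand transitions ramp between
#'   the two synchronously with the flexion ramp.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(name, rom_min, rom_max, rate,
                             waveform = c("periodic", "half_cycle_down",
                                          "half_cycle_up", "quasi_static"),
                             femoral_share = 0.3, impact_amplitude = 0,
                             thigh_start = 0, thigh_end = 0) {
  waveform <- match.arg(waveform)
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(rom_min) || !is.numeric(rom_max) || rom_min >= rom_max)
    stop("activity_profile: need rom_min < rom_max (got ",
         rom_min, ", ", rom_max, ")")
  if (!is.numeric(rate) || rate <= 0 || rate > 2)
    stop("activity_profile: rate must lie in (0, 2] Hz, got ", rate)
  if (femoral_share < 0 || femoral_share > 1)
    stop("activity_profile: femoral_share must lie in [0, 1]")
  structure(list(name = name, rom_min = rom_min, rom_max = rom_max,
                 rate = rate, waveform = waveform,
                 femoral_share = femoral_share,
                 impact_amplitude = impact_amplitude,
                 thigh_start = thigh_start, thigh_end = thigh_end),
            class = "activity_profile")
}

#' Default kinematic profiles for the eight activities
#'
#' Flexion ranges and tested cycle rates follow the published simulated-knee
#' movement table: walking 7--62 deg at 0.94 Hz, jogging 7--62 at 1.4, stair
#' ascent 13--94 at 0.56, stair descent 14--98 at 0.58, sitting down 6--94 at
#' 0.16, standing up 6--94 at 0.16, knee bending 4--98 at 0.13, and standing
#' still 7--13 at 0.1 Hz. Femoral shares and thigh-inclination ramps are the
#' package's own rigid-body stand-in (see the methods vignette): stair ascent
#' is thigh-dominant, stair descent shank-dominant, sit/stand transitions
#' carry a 0--90 degree thigh ramp, and knee bending keeps the thigh near
#' vertical.
#'
#' @return Named list of eight [activity_profile()] objects, in
#'   [adl_classes()] order.
#' @export
default_profiles <- function() {
  p <- list(
    jogging        = activity_profile("jogging", 7, 62, 1.4, "periodic",
                                      femoral_share = 0.35,
                                      impact_amplitude = 3),
    knee_bending   = activity_profile("knee_bending", 4, 98, 0.13,
                                      "half_cycle_down",
                                      femoral_share = 0.10),
    sitting_down   = activity_profile("sitting_down", 6, 94, 0.16,
                                      "half_cycle_down",
                                      femoral_share = 0.30,
                                      thigh_start = 0, thigh_end = 90),
    standing_up    = activity_profile("standing_up", 6, 94, 0.16,
                                      "half_cycle_up",
                                      femoral_share = 0.30,
                                      thigh_start = 90, thigh_end = 0),
    walking        = activity_profile("walking", 7, 62, 0.94, "periodic",
                                      femoral_share = 0.35),
    standing_still = activity_profile("standing_still", 7, 13, 0.1,
                                      "quasi_static",
                                      femoral_share = 0.10),
    stair_ascent   = activity_profile("stair_ascent", 13, 94, 0.56,
                                      "periodic", femoral_share = 0.45),
    stair_descent  = activity_profile("stair_descent", 14, 98, 0.58,
                                      "periodic", femoral_share = 0.25)
  )
  p[adl_classes()]
}

#' Knee flexion angle waveform
#'
#' Evaluates the flexion angle theta(t) for an activity profile. Periodic and
#' quasi-static profiles oscillate between `rom_min` and `rom_max` as a
#' raised cosine at the profile rate, starting from the cycle minimum at
#' `t = 0`, `phase = 0`. Half-cycle profiles traverse a single monotone
#' raised-cosine ramp of duration `1 / (2 * rate)` (min to max for
#' `half_cycle_down`, max to min for `half_cycle_up`) and hold the final
#' angle thereafter.
#'
#' @param profile an [activity_profile()].
#' @param t time in seconds (vectorised); all values must be `>= 0`.
#' @param phase phase offset in radians (periodic waveforms only).
#' @return Flexion angle(s) in degrees, always within
#'   `[rom_min, rom_max]`.
#' @export
flexion_waveform <- function(profile, t, phase = 0) {
  stopifnot(inherits(profile, "activity_profile"))
  if (any(t < 0)) stop("flexion_waveform: t must be non-negative")
  rng <- profile$rom_max - profile$rom_min
  switch(profile$waveform,
    periodic = ,
    quasi_static = {
      profile$rom_min +
        rng * (1 - cos(2 * pi * profile$rate * t + phase)) / 2
    },
    half_cycle_down = {
      T_half <- 1 / (2 * profile$rate)
      s <- pmin(t, T_half)
      profile$rom_min + rng * (1 - cos(pi * s / T_half)) / 2
    },
    half_cycle_up = {
      T_half <- 1 / (2 * profile$rate)
      s <- pmin(t, T_half)
      profile$rom_max - rng * (1 - cos(pi * s / T_half)) / 2
    }
  )
}
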