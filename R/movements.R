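#' Cosine trajectory weight
#'
#' The normalized joint-angle waveform used for every joint: a half-period
#' cosine `w(t) = (1 + cos(pi * t / duration)) / 2`, equal to 1 at seat-off
#' and 0 at the standing posture. Each joint angle during the movement is the
#' seat-off angle multiplied by this weight.
#'
#' @param t time in s (scalar or vector)
#' @param duration movement duration in s
#' @return weight in `[0, 1]`
#' @export
cosine_weight <- function(t, duration) (1 + cos(pi * t / duration)) / 2

cosine_weight_d1 <- function(t, duration) -pi / (2 * duration) * sin(pi * t / duration)

cosine_weight_d2 <- function(t, duration) -pi^2 / (2 * duration^2) * cos(pi * t / duration)

#' Generate STS movements from a seat-off posture grid
#'
#' Attaches a cosine-curve trajectory (seat-off to upright standing, all
#' joint angles reaching zero) to every posture of the grid. The trajectory
#' of each joint angle is its seat-off value times [cosine_weight()].
#'
#' @param body a [build_body_model()] object
#' @param grid a posture grid from [generate_posture_grid()]; defaults to the
#'   full grid for `body`
#' @param duration movement time from seat-off to standing in s (default 1.55)
#' @param n_frames number of time samples (default 101)
#' @return an object of class `sts_movements`: the grid plus time base and
#'   normalized waveform; angle series are materialized by [angle_series()]
#' @export
generate_movements <- function(body, grid = generate_posture_grid(body),
                               duration = 1.55, n_frames = 101) {
  stopifnot(n_frames >= 3, duration > 0)
  t <- seq(0, duration, length.out = n_frames)
  mov <- list(
    body = body,
    postures = grid,
    duration = duration,
    n_frames = n_frames,
    t = t,
    w = cosine_weight(t, duration),
    wd = cosine_weight_d1(t, duration),
    wdd = cosine_weight_d2(t, duration),
    adopted = rep(NA, nrow(grid)),
    normal = rep(NA, nrow(grid)),
    exclusion_reason = rep(NA_character_, nrow(grid))
  )
  class(mov) <- "sts_movements"
  mov
}

#' @export
print.sts_movements <- function(x, ...) {
  cat(sprintf("STS movement set: %d postures, duration %.2f s, %d frames\n",
              nrow(x$postures), x$duration, x$n_frames))
  if (!all(is.na(x$adopted))) {
    cat(sprintf("  adopted: %d, normal: %d\n",
                sum(x$adopted, na.rm = TRUE), sum(x$normal, na.rm = TRUE)))
  }
  invisible(x)
}

#' Joint-angle time series of a movement set
#'
#' @param mov an `sts_movements` object
#' @param which indices of movements (default all)
#' @return list with matrices `hip`, `knee`, `ankle` (movements x frames,
#'   degrees)
#' @export
angle_series <- function(mov, which = seq_len(nrow(mov$postures))) {
  p <- mov$postures[which, ]
  list(hip = outer(p$hip_deg, mov$w),
       knee = outer(p$knee_deg, mov$w),
       ankle = outer(p$ankle_deg, mov$w))
}

#' Whole-body centre-of-mass X trajectory
#'
#' Mass-weighted mean X coordinate of all segment COMs (bilateral leg
#' segments counted twice), per movement and frame.
#'
#' @param mov an `sts_movements` object
#' @param body the body model (defaults to the one in `mov`)
#' @param which movement indices (default all)
#' @return matrix (movements x frames) of COM X positions in m
#' @export
whole_body_com_x <- function(mov, body = mov$body,
                             which = seq_len(nrow(mov$postures))) {
  kin <- movement_kinematics(mov, body, which = which, derivatives = FALSE)
  com_x_from_kinematics(kin, body)
}

com_x_from_kinematics <- function(kin, body) {
  m_hat <- body$hat$mass
  m_th <- 2 * body$thigh$mass
  m_sh <- 2 * body$shank$mass
  m_ft <- 2 * body$foot$mass
  fc <- foot_com(body)
  (m_hat * kin$hat_com_x + m_th * kin$thigh_com_x +
     m_sh * kin$shank_com_x + m_ft * fc[1]) / body$mass
}

#' Apply the adoption filters to a movement set
#'
#' A movement is adopted iff (a) its seat-off hip, knee and ankle angles lie
#' within the closed ranges 85-145 deg flexion, 95-120 deg flexion and 15-45
#' deg dorsiflexion, and (b) the whole-body centre of mass stays within the
#' foot-length support base (heel to toe) at every frame of the trajectory.
#' Geometrically impossible postures are never adopted.
#'
#' @param mov an `sts_movements` object
#' @param hip_range,knee_range,ankle_range closed adoption intervals (deg)
#' @return `mov` with `adopted` flags and `exclusion_reason` filled in
#' @export
apply_adoption_filters <- function(mov,
                                   hip_range = c(85, 145),
                                   knee_range = c(95, 120),
                                   ankle_range = c(15, 45)) {
  p <- mov$postures
  in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  angles_ok <- in_range(p$hip_deg, hip_range) &
    in_range(p$knee_deg, knee_range) &
    in_range(p$ankle_deg, ankle_range)
  reason <- rep(NA_character_, nrow(p))
  reason[!p$valid] <- "invalid_geometry"
  reason[p$valid & !angles_ok] <- "seatoff_angles"
  # COM filter only needs evaluating where the angle filter passed
  candidate <- which(p$valid & angles_ok)
  com_ok <- rep(FALSE, nrow(p))
  if (length(candidate) > 0) {
    base <- support_base(mov$body)
    cx <- whole_body_com_x(mov, which = candidate)
    inside <- cx >= base[1] & cx <= base[2]
    com_ok[candidate] <- apply(inside, 1, all)
    reason[candidate][!com_ok[candidate]] <- "com_outside_support_base"
  }
  mov$adopted <- p$valid & angles_ok & com_ok
  mov$exclusion_reason <- reason
  mov$normal <- classify_normal(p$hip_deg) & mov$adopted
  mov
}

#' Classify normal STS movements
#'
#' A movement is "normal" when its seat-off hip flexion angle lies within
#' 93 +/- 8 degrees (closed interval), the band reported for natural
#' sit-to-stand transfers.
#'
#' @param hip_deg seat-off hip flexion angle(s) in degrees
#' @param band centre and half-width of the band (degrees)
#' @return logical vector
#' @export
classify_normal <- function(hip_deg, band = c(93, 8)) {
  !is.na(hip_deg) & hip_deg >= band[1] - band[2] & hip_deg <= band[1] + band[2]
}
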