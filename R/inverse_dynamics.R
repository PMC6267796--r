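# 2-D Newton-Euler inverse dynamics on the prescribed cosine kinematics.
#
# Top-down recursive pass per leg: the HAT load is split 50/50 over the two
# (identical) legs, so each leg carries half the HAT mass and inertia.
# Moments are reported per leg, normalized by whole-body mass (Nm/kg), with
# hip extension, knee extension and ankle plantarflexion positive. The hip
# intersegmental force is the force applied to the femoral head by the
# pelvis side (N/kg).

cross_z <- function(ax, ay, bx, by) ax * by - ay * bx

#' Joint moments and hip intersegmental force
#'
#' Runs the top-down Newton-Euler pass (half-HAT -> hip -> thigh -> knee ->
#' shank -> ankle) for the selected movements on the analytic cosine
#' kinematics. With `static = TRUE` all velocities and accelerations are
#' zeroed and the gravity-only (static-component) moments are returned.
#'
#' @param mov an `sts_movements` object
#' @param body body model (defaults to the one inside `mov`)
#' @param which movement indices (default all)
#' @param static zero all velocities and accelerations (gravity only)
#' @param gravity gravitational acceleration, m/s^2
#' @return an object of class `sts_kinetics`: list of movements x frames
#'   matrices `hip_moment`, `knee_moment`, `ankle_moment` (Nm/kg, extension /
#'   plantarflexion positive), `hjf_x`, `hjf_y` (hip intersegmental force on
#'   the femur, N/kg), plus the kinematics used
#' @export
compute_joint_moments <- function(mov, body = mov$body,
                                  which = seq_len(nrow(mov$postures)),
                                  static = FALSE, gravity = GRAVITY) {
  kin <- movement_kinematics(mov, body, which = which, derivatives = !static)
  if (static) {
    zero <- kin$theta_s * 0
    for (nm in c("shank_com_acc_x", "shank_com_acc_y", "thigh_com_acc_x",
                 "thigh_com_acc_y", "hat_com_acc_x", "hat_com_acc_y",
                 "alpha_s", "alpha_th", "alpha_tr")) {
      kin[[nm]] <- zero
    }
  }
  newton_euler_top_down(kin, body, gravity = gravity)
}

newton_euler_top_down <- function(kin, body, gravity = GRAVITY) {
  m_hat2 <- body$hat$mass / 2
  I_hat2 <- segment_inertia(body$hat) / 2
  m_th <- body$thigh$mass
  I_th <- segment_inertia(body$thigh)
  m_sh <- body$shank$mass
  I_sh <- segment_inertia(body$shank)
  A <- c(0, body$ankle_height)

  # HAT (half): only the hip acts on it
  F_hip_x <- m_hat2 * kin$hat_com_acc_x
  F_hip_y <- m_hat2 * (kin$hat_com_acc_y + gravity)
  M_hip <- I_hat2 * kin$alpha_tr -
    cross_z(kin$hip_x - kin$hat_com_x, kin$hip_y - kin$hat_com_y,
            F_hip_x, F_hip_y)

  # thigh: hip reaction from the HAT side plus knee unknowns
  F_knee_x <- m_th * kin$thigh_com_acc_x + F_hip_x
  F_knee_y <- m_th * (kin$thigh_com_acc_y + gravity) + F_hip_y
  M_knee <- I_th * kin$alpha_th + M_hip -
    cross_z(kin$hip_x - kin$thigh_com_x, kin$hip_y - kin$thigh_com_y,
            -F_hip_x, -F_hip_y) -
    cross_z(kin$knee_x - kin$thigh_com_x, kin$knee_y - kin$thigh_com_y,
            F_knee_x, F_knee_y)

  # shank: knee reaction from the thigh side plus ankle unknowns
  F_ankle_x <- m_sh * kin$shank_com_acc_x + F_knee_x
  F_ankle_y <- m_sh * (kin$shank_com_acc_y + gravity) + F_knee_y
  M_ankle <- I_sh * kin$alpha_s + M_knee -
    cross_z(kin$knee_x - kin$shank_com_x, kin$knee_y - kin$shank_com_y,
            -F_knee_x, -F_knee_y) -
    cross_z(A[1] - kin$shank_com_x, A[2] - kin$shank_com_y,
            F_ankle_x, F_ankle_y)

  M <- body$mass
  out <- list(
    hip_moment = M_hip / M,       # extension positive (+z on HAT)
    knee_moment = -M_knee / M,    # extension positive (-z on thigh at knee)
    ankle_moment = M_ankle / M,   # plantarflexion positive (+z on shank)
    hjf_x = -F_hip_x / M,         # force on femur from the pelvis side
    hjf_y = -F_hip_y / M,
    kin = kin, body = body, gravity = gravity
  )
  class(out) <- "sts_kinetics"
  out
}

#' @export
print.sts_kinetics <- function(x, ...) {
  cat(sprintf("STS joint kinetics: %d movements x %d frames\n",
              nrow(x$hip_moment), ncol(x$hip_moment)))
  cat(sprintf("  peak hip extension moment range: %.3f .. %.3f Nm/kg\n",
              min(apply(x$hip_moment, 1, max)),
              max(apply(x$hip_moment, 1, max))))
  invisible(x)
}

#' Gravity-only (static-component) joint moments
#'
#' Convenience wrapper: [compute_joint_moments()] with all velocities and
#' accelerations zeroed.
#'
#' @inheritParams compute_joint_moments
#' @return an `sts_kinetics` object (see [compute_joint_moments()])
#' @export
static_moment_component <- function(mov, body = mov$body,
                                    which = seq_len(nrow(mov$postures)),
                                    gravity = GRAVITY) {
  compute_joint_moments(mov, body, which = which, static = TRUE,
                        gravity = gravity)
}

#' Hip intersegmental force series
#'
#' @inheritParams compute_joint_moments
#' @return list with matrices `x` and `y` (N/kg): the force applied to the
#'   femoral head by the pelvis side, per leg, normalized by body mass
#' @export
hip_joint_force <- function(mov, body = mov$body,
                            which = seq_len(nrow(mov$postures)),
                            gravity = GRAVITY) {
  k <- compute_joint_moments(mov, body, which = which, gravity = gravity)
  list(x = k$hjf_x, y = k$hjf_y)
}
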